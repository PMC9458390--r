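## The 46-feature KS descriptor: 19 energy features (wavelet-packet band
## ratios and per-beat variability), 12 time/frequency statistics, 2
## entropies, and 13 Mel-frequency cepstral coefficients, all computed on
## the denoised record restricted to the detected span [B, E].

.energy_names <- c("Stotal_50_100", "Stotal_100_150", "Stotal_150_200",
                   "Stotal_200_250", "Stotal_250_300", "Stotal_300_350",
                   "Stotal_350_400",
                   "std_enr", "std_enr_h", "std_TM", "std_Ep",
                   "enr_max", "enr_min", "enr_h_max", "enr_h_min",
                   "TM_max", "TM_min", "Ep_max", "Ep_min")
.stat_names <- c("mean", "median", "std", "mean_abs_dev", "q1", "q3", "iqr",
                 "skewness", "kurtosis", "dom_freq", "dom_freq_mag",
                 "dom_freq_ratio")
.entropy_names <- c("H_signal", "H_freq")
.mfcc_names <- paste0("c", 1:13)

#' Names of the features in each feature set
#'
#' Set A holds the energy, statistical and entropy features (33); set B the
#' statistical, entropy and MFCC features (27); set C all 46.
#'
#' @param set One of `"A"`, `"B"`, `"C"`.
#' @return Character vector of feature names.
#' @export
feature_set_names <- function(set = c("C", "A", "B")) {
  set <- match.arg(set)
  switch(set,
         A = c(.energy_names, .stat_names, .entropy_names),
         B = c(.stat_names, .entropy_names, .mfcc_names),
         C = c(.energy_names, .stat_names, .entropy_names, .mfcc_names))
}

#' Global energy ratios over the seven 50-400 Hz bands
#'
#' `S_total(j) = E(j) / E_total`, where the total runs over the seven 50 Hz
#' bands at and above 50 Hz; the 0-50 Hz node is excluded. Ratios sum to 1.
#'
#' @param bands A `band_energies` from [wp_band_energies()].
#' @return Named length-7 vector of fractions summing to 1.
#' @export
global_band_ratios <- function(bands) {
  if (bands$total_50_400 <= 0) stop("zero energy in 50-400 Hz")
  bands$node_energies[2:8] / bands$total_50_400
}

#' Per-beat band-energy ratios
#'
#' For one beat window: `en` = E(50-100)/E(50-400) (low-frequency ratio),
#' `en_h` = E(150-400)/E(50-400) (high-frequency ratio), `Et` = E(50-400)
#' (total energy). The 100-150 Hz band belongs to neither ratio, so
#' `en + E(100-150)/E(50-400) + en_h = 1`.
#'
#' @param beat Numeric beat-window signal at the working rate.
#' @param wavelet_name Orthogonal wavelet name.
#' @param rate Sampling rate in Hz.
#' @return Named vector `c(en, en_h, Et)`.
#' @export
beat_band_ratios <- function(beat, wavelet_name = "db8", rate = 800) {
  b <- wp_band_energies(beat, wavelet_name, rate)
  tot <- b$total_50_400
  if (tot <= 0) stop("beat has zero energy in 50-400 Hz")
  e <- b$node_energies
  c(en = unname(e[2]) / tot,
    en_h = unname(sum(e[4:8])) / tot,
    Et = tot)
}

#' Mean-normalise a per-beat series
#'
#' Divides each value by the series mean, so the output has mean exactly 1.
#' This is the variability normalisation applied to the per-beat energy
#' ratios and inter-beat intervals (enr, enr_h, Ep, TM).
#'
#' @param values Non-empty numeric vector with positive mean.
#' @return Numeric vector of the same length with mean 1.
#' @export
variability_series <- function(values) {
  if (length(values) == 0L) stop("empty series")
  mu <- mean(values)
  if (mu <= 0) stop("series mean must be positive")
  values / mu
}

#' The 19 energy features
#'
#' Combines the seven global band ratios (as percentages) with the spread and
#' extrema of the per-beat series: `std_enr`/`std_enr_h` are the standard
#' deviations of `en`/`en_h` x100 and `enr_max` etc. their extrema x100
#' (fractions of unity, so percentages); `std_Ep`/`std_TM` and the
#' `Ep`/`TM` extrema are taken on the mean-normalised total-energy and
#' interval series x100, so a perfectly regular train scores exactly 100.
#'
#' @param en,en_h,Et Per-beat low ratio, high ratio and total energy
#'   (length >= 2).
#' @param Ti Inter-beat intervals in s (length >= 1).
#' @param global_ratios Length-7 fractions from [global_band_ratios()].
#' @return Named length-19 numeric vector.
#' @export
energy_feature_block <- function(en, en_h, Et, Ti, global_ratios) {
  if (length(en) < 2L || length(Et) < 2L || length(Ti) < 1L)
    stop("insufficient beats (need >= 2 beats for variability features)")
  Ep <- variability_series(Et) * 100
  TM <- variability_series(Ti) * 100
  out <- c(global_ratios * 100,
           std_enr = stats::sd(en) * 100,
           std_enr_h = stats::sd(en_h) * 100,
           std_TM = stats::sd(TM),
           std_Ep = stats::sd(Ep),
           enr_max = max(en) * 100, enr_min = min(en) * 100,
           enr_h_max = max(en_h) * 100, enr_h_min = min(en_h) * 100,
           TM_max = max(TM), TM_min = min(TM),
           Ep_max = max(Ep), Ep_min = min(Ep))
  names(out) <- .energy_names
  out
}

#' The 12 statistical features
#'
#' Time-domain moments and quantiles of the amplitude samples plus the
#' dominant spectral peak in 50-400 Hz: `dom_freq` is the periodogram argmax
#' (Hz), `dom_freq_mag` the peak power as a fraction of total periodogram
#' power, and `dom_freq_ratio` the peak power as a fraction of 50-400 Hz
#' power. Skewness is the standardised third moment and kurtosis the Pearson
#' (non-excess) fourth; both are set to 0 with a warning when the signal is
#' degenerate (zero variance). Quartiles use linear interpolation.
#'
#' @param x Numeric signal over the detected span (length >= 8).
#' @param rate Sampling rate in Hz.
#' @param band Frequency band for the dominant peak, Hz.
#' @return Named length-12 numeric vector.
#' @export
statistical_features <- function(x, rate = 800, band = c(50, 400)) {
  if (length(x) < 8L) stop("signal too short for statistical features")
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  if (m2 == 0) {
    warning("degenerate signal: skewness and kurtosis set to 0")
    skew <- 0; kurt <- 0
  } else {
    skew <- mean((x - mu)^3) / m2^1.5
    kurt <- mean((x - mu)^4) / m2^2
  }
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE, type = 7)

  p <- periodogram_power(x)
  f <- (seq_along(p) - 1) / length(x) * rate      # one-sided bin freqs
  inb <- f >= band[1] & f <= band[2]
  tot_band <- sum(p[inb])
  tot_all <- sum(p)
  if (tot_band > 0) {
    k <- which(inb)[which.max(p[inb])]
    dom_freq <- f[k]
    dom_mag <- p[k] / tot_all
    dom_ratio <- p[k] / tot_band
  } else {
    dom_freq <- 0; dom_mag <- 0; dom_ratio <- 0
  }
  out <- c(mu, stats::median(x), stats::sd(x), mean(abs(x - mu)),
           q[1], q[2], q[2] - q[1], skew, kurt,
           dom_freq, dom_mag, dom_ratio)
  names(out) <- .stat_names
  out
}

## one-sided raw periodogram (power per positive-frequency bin incl. DC)
periodogram_power <- function(x) {
  n <- length(x)
  p <- Mod(stats::fft(x))^2 / n
  p[seq_len(n %/% 2L + 1L)]
}

#' Signal and frequency entropy
#'
#' `H_signal` is the Shannon entropy (bits) of the amplitude histogram with
#' `bins` equal-width bins over the signal's range; `H_freq` is the entropy
#' of the one-sided periodogram normalised to a probability distribution.
#' Empty bins contribute zero. A pure tone concentrates spectral mass in one
#' bin and scores a low `H_freq`; broadband noise scores high.
#'
#' @param x Numeric signal (length >= `bins` recommended).
#' @param bins Histogram bin count (default 128).
#' @return Named vector `c(H_signal, H_freq)` in bits.
#' @export
entropy_features <- function(x, bins = 128L) {
  rng <- range(x)
  if (rng[1] == rng[2]) {
    hs <- 0                                    # all mass in one bin
  } else {
    cuts <- seq(rng[1], rng[2], length.out = bins + 1L)
    counts <- tabulate(findInterval(x, cuts, rightmost.closed = TRUE,
                                    all.inside = TRUE), nbins = bins)
    hs <- shannon_entropy_bits(counts / length(x))
  }
  p <- periodogram_power(x)
  tot <- sum(p)
  hf <- if (tot > 0) shannon_entropy_bits(p / tot) else 0
  c(H_signal = hs, H_freq = hf)
}

shannon_entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Mel-frequency cepstral coefficients
#'
#' Frame-wise MFCCs on the working-rate signal: 40 ms Hann frames with 50%
#' overlap, power spectra on a zero-padded FFT, `M` triangular Mel filters
#' spanning 0 to `rate`/2, log filter energies, then the DCT
#' `c(n1) = sum_m log E(m) cos((m - 0.5)/M * n1 * pi)` for `n1 = 1..L`,
#' averaged over frames. Filter energies are floored at a tiny fraction of
#' the frame total, which keeps the coefficients exactly invariant to
#' waveform gain (a gain shifts every log energy by the same constant, and
#' the DCT of a constant vanishes for `n1 >= 1`).
#'
#' @param x Numeric signal at the working rate (at least one frame).
#' @param rate Sampling rate in Hz.
#' @param M Number of Mel filters (>= `L`).
#' @param L Number of coefficients (default 13).
#' @param frame_len Frame length in s.
#' @param overlap Fractional overlap.
#' @param nfft FFT length (zero-padded).
#' @return Named length-`L` numeric vector `c1..cL`.
#' @export
mfcc_features <- function(x, rate = 800, M = 26L, L = 13L,
                          frame_len = 0.040, overlap = 0.5, nfft = 256L) {
  if (M < L) stop("need at least as many Mel filters as coefficients (M >= L)")
  Ln <- round(frame_len * rate)
  H <- round(Ln * (1 - overlap))
  if (length(x) < Ln) stop("signal shorter than one analysis frame")
  n_frames <- floor((length(x) - Ln) / H) + 1L
  starts <- (seq_len(n_frames) - 1L) * H
  w <- hann_periodic(Ln)
  fm <- vapply(starts, function(s) c(x[(s + 1L):(s + Ln)] * w,
                                     numeric(nfft - Ln)), numeric(nfft))
  spec <- Mod(stats::mvfft(matrix(fm, nrow = nfft)))^2
  spec <- spec[seq_len(nfft %/% 2L + 1L), , drop = FALSE]

  fb <- mel_filterbank(M, nfft, rate)            # M x bins
  E <- fb %*% spec                               # M x n_frames
  tot <- colSums(E)
  floor_mat <- matrix(pmax(tot, .Machine$double.xmin) * 1e-12,
                      nrow = M, ncol = n_frames, byrow = TRUE)
  logE <- log(pmax(E, floor_mat))
  dct <- outer(seq_len(L), seq_len(M),
               function(n1, m) cos((m - 0.5) / M * n1 * pi)) # L x M
  co <- rowMeans(dct %*% logE)
  names(co) <- paste0("c", seq_len(L))
  co
}

## triangular Mel filterbank, M filters over [0, rate/2], rows sum over bins
mel_filterbank <- function(M, nfft, rate) {
  mel <- function(f) 2595 * log10(1 + f / 700)
  imel <- function(m) 700 * (10^(m / 2595) - 1)
  edges <- imel(seq(mel(0), mel(rate / 2), length.out = M + 2L))
  bins <- (seq_len(nfft %/% 2L + 1L) - 1) * rate / nfft
  fb <- matrix(0, nrow = M, ncol = length(bins))
  for (m in seq_len(M)) {
    lo <- edges[m]; ce <- edges[m + 1L]; hi <- edges[m + 2L]
    rise <- (bins - lo) / (ce - lo)
    fall <- (hi - bins) / (hi - ce)
    fb[m, ] <- pmax(0, pmin(rise, fall))
  }
  fb
}

#' Extract the full 46-feature vector from a KS record
#'
#' Runs the whole chain: peak normalisation, resampling to the working rate,
#' Wiener denoising, Shannon-envelope segmentation, then the four feature
#' blocks. The statistical, entropy and MFCC blocks are computed on the
#' denoised signal restricted to the detected span \[B, E\].
#'
#' @param record An [audio_record].
#' @param config A [run_config()].
#' @return A named length-46 numeric vector of class `feature_vector`, with
#'   attributes `segmentation` (the `record_segmentation`) and `config`.
#' @export
extract_features <- function(record, config = run_config()) {
  peak <- max(abs(record$samples))
  if (peak == 0) stop("all-zero record")
  rec <- audio_record(record$samples / peak, record$rate,
                      source_id = record$source_id, label = record$label)
  rec <- resample_record(rec, config$working_rate)
  den <- denoise_record(rec, config)
  seg <- segment_record(den, config)
  n_beats <- length(seg$anchors$times)
  if (n_beats < 2L)
    stop("insufficient beats: ", n_beats, " anchor(s) detected")

  rate <- config$working_rate
  span_idx <- (floor(seg$B * rate) + 1L):min(length(den$samples),
                                             ceiling(seg$E * rate))
  xs <- den$samples[span_idx]

  bands <- wp_band_energies(xs, config$wavelet_name, rate)
  gratios <- global_band_ratios(bands)

  beat_mat <- vapply(seq_len(n_beats), function(i) {
    idx <- (floor(seg$beat_windows[i, 1] * rate) + 1L):
      min(length(den$samples), ceiling(seg$beat_windows[i, 2] * rate))
    beat_band_ratios(den$samples[idx], config$wavelet_name, rate)
  }, numeric(3))

  energy <- energy_feature_block(beat_mat["en", ], beat_mat["en_h", ],
                                 beat_mat["Et", ], seg$intervals, gratios)
  stats12 <- statistical_features(xs, rate)
  ent2 <- entropy_features(xs, config$entropy_bins)
  mfcc13 <- mfcc_features(xs, rate, M = config$mfcc_filters,
                          frame_len = config$frame_len,
                          overlap = config$frame_overlap)

  fv <- c(energy, stats12, ent2, mfcc13)
  stopifnot(identical(names(fv), feature_set_names("C")))
  if (any(!is.finite(fv))) stop("non-finite feature(s): ",
                                paste(names(fv)[!is.finite(fv)], collapse = ", "))
  structure(fv, class = "feature_vector", segmentation = seg, config = config)
}

#' Project a feature vector (or matrix) onto a feature set
#'
#' @param x A `feature_vector` or a matrix/data.frame with the 46 feature
#'   columns.
#' @param set `"A"`, `"B"` or `"C"`.
#' @return The subset, in set order.
#' @export
feature_subset <- function(x, set = "C") {
  nm <- feature_set_names(set)
  if (is.null(dim(x))) x[nm] else x[, nm, drop = FALSE]
}
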