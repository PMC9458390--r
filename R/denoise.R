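## Wiener denoising of KS records.
##
## The minimum-mean-square-error criterion is realised in the frequency
## domain: short Hann-windowed frames, a noise power spectrum estimated from
## the silent lead-in, per-bin gains from the decision-directed a-priori SNR
## rule, and overlap-add resynthesis. Gains are bounded in [floor, 1] so the
## filter can only attenuate.

#' Estimate a noise power spectrum from the silent lead-in
#'
#' KS measurements begin with a silent phase before the first Korotkoff sound
#' appears; its broadband content is taken as the noise reference. The
#' profile is the average periodogram of the first `n_frames` Hann-windowed
#' frames.
#'
#' @param record An [audio_record].
#' @param n_frames Number of leading frames to average; if `NULL`, as many
#'   frames as fit in `noise_seconds` of audio.
#' @param frame_len Frame length in seconds.
#' @param noise_seconds Lead-in length used when `n_frames` is `NULL`.
#' @return A `noise_profile`: list with `psd` (per-bin noise power, length =
#'   FFT bins), `n_frames_used`, `frame_len`, `rate`.
#' @export
estimate_noise <- function(record, n_frames = NULL, frame_len = 0.040,
                           noise_seconds = 0.5) {
  L <- max(2L, round(frame_len * record$rate))
  H <- L %/% 2L
  if (is.null(n_frames))
    n_frames <- max(1L, floor((noise_seconds * record$rate - L) / H) + 1L)
  n_avail <- floor((length(record$samples) - L) / H) + 1L
  if (n_avail < n_frames)
    stop("record too short for ", n_frames, " noise frames (has ",
         max(0L, n_avail), ")")
  w <- hann_periodic(L)
  psd <- numeric(L)
  for (j in seq_len(n_frames)) {
    seg <- record$samples[((j - 1L) * H + 1L):((j - 1L) * H + L)]
    psd <- psd + Mod(stats::fft(seg * w))^2
  }
  structure(list(psd = psd / n_frames, n_frames_used = as.integer(n_frames),
                 frame_len = frame_len, rate = record$rate),
            class = "noise_profile")
}

#' Wiener-filter a KS record
#'
#' Frequency-domain Wiener filter: per-bin gain `xi / (1 + xi)` with the
#' a-priori SNR `xi` tracked by the decision-directed rule (smoothing 0.98)
#' and floored at `gain_floor`. A zero noise profile yields unit gain, so the
#' output then equals the input to numerical precision.
#'
#' @param record An [audio_record].
#' @param profile A `noise_profile` from [estimate_noise()], built at the
#'   same rate and frame length.
#' @param gain_floor Lower bound on the spectral gain (default 0.05).
#' @param alpha Decision-directed smoothing constant (default 0.98).
#' @return The denoised [audio_record] (same length and rate).
#' @export
wiener_filter <- function(record, profile, gain_floor = 0.05, alpha = 0.98) {
  if (!inherits(profile, "noise_profile")) stop("profile must be a noise_profile")
  if (profile$rate != record$rate)
    stop("noise profile rate (", profile$rate, ") does not match record rate (",
         record$rate, ")")
  L <- length(profile$psd)
  if (L != max(2L, round(profile$frame_len * record$rate)))
    stop("noise profile frame geometry does not match its rate")
  H <- L %/% 2L
  x <- record$samples
  n <- length(x)
  ## pad one hop at both ends so every true sample has full window coverage
  ## (the Hann window is zero at its first point)
  n_frames <- ceiling(max(n + H - L, 0) / H) + 2L
  pad <- (n_frames - 1L) * H + L
  xp <- c(numeric(H), x, numeric(pad - n - H))
  w <- hann_periodic(L)
  noise <- pmax(profile$psd, .Machine$double.eps * sum(profile$psd))
  all_zero_noise <- all(profile$psd == 0)

  out <- numeric(pad)
  wsum <- numeric(pad)
  prev_gain2_gamma <- rep(1, L)
  for (j in seq_len(n_frames)) {
    idx <- ((j - 1L) * H + 1L):((j - 1L) * H + L)
    spec <- stats::fft(xp[idx] * w)
    if (all_zero_noise) {
      gain <- rep(1, L)
    } else {
      gamma <- Mod(spec)^2 / noise                      # a-posteriori SNR
      xi <- alpha * prev_gain2_gamma + (1 - alpha) * pmax(gamma - 1, 0)
      gain <- pmin(pmax(xi / (1 + xi), gain_floor), 1)
      prev_gain2_gamma <- gain^2 * gamma
    }
    rec <- Re(stats::fft(spec * gain, inverse = TRUE)) / L
    out[idx] <- out[idx] + rec * w
    wsum[idx] <- wsum[idx] + w^2
  }
  span <- (H + 1L):(H + n)
  y <- out[span] / pmax(wsum[span], .Machine$double.eps)
  audio_record(clip_unit(y), record$rate, source_id = record$source_id,
               label = record$label)
}

#' Denoise a record using its own silent lead-in
#'
#' Convenience wrapper: estimates the noise profile from the first
#' `noise_seconds` of the record and applies [wiener_filter()].
#'
#' @param record An [audio_record].
#' @param config A [run_config()].
#' @return The denoised [audio_record].
#' @export
denoise_record <- function(record, config = run_config()) {
  profile <- estimate_noise(record, frame_len = config$frame_len,
                            noise_seconds = config$noise_seconds)
  wiener_filter(record, profile)
}

hann_periodic <- function(L) 0.5 - 0.5 * cos(2 * pi * (0:(L - 1L)) / L)
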