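# Shared fixtures, built once per test run and cached.

.fx <- new.env(parent = emptyenv())

fx_get <- function(name, builder) {
  if (!exists(name, envir = .fx)) assign(name, builder(), envir = .fx)
  get(name, envir = .fx)
}

# 50 healthy-template records at 15 dB SNR with their segmentations
fx_seg50 <- function() fx_get("seg50", function() {
  lapply(1:50, function(s) {
    g <- generate_record(healthy_spec(noise_snr_db = 15), seed = s)
    g$seg <- segment_record(denoise_record(g$record))
    g
  })
})

# contrasted 50+50 cohort and its feature table
fx_contrast <- function() fx_get("contrast", function() {
  coh <- generate_cohorts(50, healthy_spec(), chf_spec(), seed = 11)
  list(cohort = coh, table = extract_feature_table(coh))
})

# null 100+100 cohort (identical specs) and its feature table
fx_null <- function() fx_get("null", function() {
  coh <- generate_cohorts(100, healthy_spec(), healthy_spec(), seed = 23)
  list(cohort = coh, table = extract_feature_table(coh))
})

# match detected anchor times against ground truth within a tolerance
match_counts <- function(detected, truth, tol = 0.05) {
  used <- rep(FALSE, length(detected))
  tp <- 0L
  for (tt in truth) {
    d <- abs(detected - tt)
    d[used] <- Inf
    j <- which.min(d)
    if (length(detected) && d[j] <= tol) {
      tp <- tp + 1L
      used[j] <- TRUE
    }
  }
  c(tp = tp, n_det = length(detected), n_true = length(truth))
}

# independent brute-force MFCC evaluation of a single frame: naive DFT,
# naive triangular Mel filters, explicit double-loop DCT
mfcc_bruteforce <- function(frame, rate, M, L, nfft) {
  n0 <- length(frame)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(n0 - 1)) / n0)
  xw <- c(frame * w, numeric(nfft - n0))
  spec <- numeric(nfft %/% 2 + 1)
  for (k in 0:(nfft %/% 2)) {
    re <- 0; im <- 0
    for (n in 0:(nfft - 1)) {
      re <- re + xw[n + 1] * cos(2 * pi * k * n / nfft)
      im <- im - xw[n + 1] * sin(2 * pi * k * n / nfft)
    }
    spec[k + 1] <- re^2 + im^2
  }
  mel <- function(f) 2595 * log10(1 + f / 700)
  imel <- function(m) 700 * (10^(m / 2595) - 1)
  edges <- imel(seq(mel(0), mel(rate / 2), length.out = M + 2))
  bins <- (0:(nfft %/% 2)) * rate / nfft
  E <- numeric(M)
  for (m in 1:M) {
    wgt <- pmax(0, pmin((bins - edges[m]) / (edges[m + 1] - edges[m]),
                        (edges[m + 2] - bins) / (edges[m + 2] - edges[m + 1])))
    E[m] <- sum(wgt * spec)
  }
  E <- pmax(E, sum(E) * 1e-12)
  out <- numeric(L)
  for (n1 in 1:L) {
    acc <- 0
    for (m in 1:M) acc <- acc + log(E[m]) * cos((m - 0.5) / M * n1 * pi)
    out[n1] <- acc
  }
  out
}

# two-class Gaussian blobs for classifier tests
make_blobs <- function(n_per_class, shift = 3, p = 4, sd = 1, seed = 7) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per_class * p, 0, sd), ncol = p),
             matrix(rnorm(n_per_class * p, shift, sd), ncol = p))
  colnames(X) <- paste0("f", seq_len(p))
  list(X = X, y = rep(c("healthy", "chf"), each = n_per_class))
}
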