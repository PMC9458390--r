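test_that("global band ratios partition the 50-400 Hz energy", {
  eq <- structure(list(node_energies = c(0, rep(2, 7)), total_50_400 = 14),
                  class = "band_energies")
  expect_equal(unname(global_band_ratios(eq)), rep(1 / 7, 7))

  one <- structure(list(node_energies = c(0, 0, 0, 5, 0, 0, 0, 0),
                        total_50_400 = 5), class = "band_energies")
  expect_equal(unname(global_band_ratios(one)), c(0, 0, 1, 0, 0, 0, 0))
  expect_lt(abs(sum(global_band_ratios(eq)) - 1), 1e-9)

  zero <- structure(list(node_energies = numeric(8), total_50_400 = 0),
                    class = "band_energies")
  expect_error(global_band_ratios(zero), "zero energy")
})

test_that("beat band ratios match an FFT band-energy oracle on tones", {
  t <- seq(0, 0.4, by = 1 / 800)
  lo <- beat_band_ratios(sin(2 * pi * 75 * t))
  expect_gte(lo["en"], 0.6)
  expect_lte(lo["en_h"], 0.1)
  hi <- beat_band_ratios(sin(2 * pi * 300 * t))
  expect_gte(hi["en_h"], 0.6)
  expect_lte(hi["en"], 0.1)

  # FFT oracle agreement within 10 percentage points (wavelet leakage bound)
  fft_band_share <- function(x, f_lo, f_hi, rate = 800) {
    p <- Mod(stats::fft(x))^2
    f <- (seq_along(p) - 1) / length(p) * rate
    keep <- f <= rate / 2
    p <- p[keep]; f <- f[keep]
    sum(p[f >= f_lo & f < f_hi]) / sum(p[f >= 50 & f <= 400])
  }
  set.seed(6)
  for (f0 in c(75, 120, 180, 300)) {
    x <- sin(2 * pi * f0 * t) + 0.05 * rnorm(length(t))
    r <- beat_band_ratios(x)
    expect_lt(abs(r["en"] - fft_band_share(x, 50, 100)), 0.10)
    expect_lt(abs(r["en_h"] - fft_band_share(x, 150, 400)), 0.10)
  }

  # partition identity: en + mid + en_h = 1 on arbitrary beats
  for (s in 1:5) {
    set.seed(s)
    x <- rnorm(320)
    b <- wp_band_energies(x)
    r <- beat_band_ratios(x)
    mid <- unname(b$node_energies[3]) / b$total_50_400
    expect_lt(abs(r["en"] + mid + r["en_h"] - 1), 1e-9)
  }
})

test_that("variability series are mean-normalised to 1", {
  expect_equal(variability_series(rep(3, 8)), rep(1, 8))
  expect_equal(variability_series(c(2, 4)), c(2 / 3, 4 / 3))
  expect_error(variability_series(numeric(0)), "empty")
  expect_error(variability_series(c(-1, 1)), "positive")
  set.seed(9)
  for (i in 1:10) {
    v <- variability_series(runif(20, 0.5, 2))
    expect_lt(abs(mean(v) - 1), 1e-9)
  }
})

test_that("the 19 energy features handle degenerate and simple cases", {
  gr <- rep(1 / 7, 7)
  # identical beats: no variability, interval extrema pinned at 100
  e <- energy_feature_block(en = rep(0.6, 5), en_h = rep(0.2, 5),
                            Et = rep(2, 5), Ti = rep(0.8, 4),
                            global_ratios = gr)
  expect_length(e, 19L)
  expect_equal(unname(e[c("std_enr", "std_Ep", "std_TM")]), c(0, 0, 0))
  expect_equal(unname(e[c("TM_max", "TM_min")]), c(100, 100))

  e2 <- energy_feature_block(en = c(0.5, 0.7), en_h = c(0.1, 0.3),
                             Et = c(1, 3), Ti = 0.8, global_ratios = gr)
  expect_equal(unname(e2[c("Ep_max", "Ep_min")]), c(150, 50))
  expect_equal(unname(e2[c("enr_max", "enr_min")]), c(70, 50))

  expect_error(energy_feature_block(0.5, 0.1, 1, numeric(0), gr),
               "insufficient beats")
})

test_that("a programmed interval variability is recovered from segmentation", {
  # generator target: cv(Ti) = 15% -> std_TM = 15
  vals <- vapply(1:50, function(s) {
    g <- generate_record(healthy_spec(period_jitter_sd = 0.12,
                                      mean_period = 0.8,
                                      noise_snr_db = 20), seed = 100 + s)
    seg <- segment_record(denoise_record(g$record))
    stats::sd(variability_series(seg$intervals) * 100)
  }, numeric(1))
  expect_lt(abs(mean(vals) - 15), 3)
})

test_that("statistical features match closed forms and FFT oracles", {
  expect_warning(s <- statistical_features(rep(0.3, 100)), "degenerate")
  expect_equal(unname(s[c("std", "mean_abs_dev", "iqr", "skewness",
                          "kurtosis")]), rep(0, 5))
  expect_equal(unname(s["mean"]), 0.3)

  t <- seq(0, 2, by = 1 / 800)
  tone <- statistical_features(sin(2 * pi * 100 * t))
  expect_lt(abs(tone["dom_freq"] - 100), 0.5 + 1e-9)
  expect_gte(tone["dom_freq_ratio"], 0.9)

  set.seed(11)
  z <- statistical_features(rnorm(1e5))
  expect_lt(abs(z["skewness"]), 0.05)
  expect_lt(abs(z["kurtosis"] - 3), 0.1)      # Pearson, non-excess
})

test_that("entropies hit their closed-form extremes and order tone vs noise", {
  # equal counts in every bin -> log2(bins)
  u <- rep(seq(0.5 / 16, 1 - 0.5 / 16, length.out = 16), times = 10)
  expect_equal(unname(entropy_features(u, bins = 16L)["H_signal"]), 4)
  expect_equal(unname(entropy_features(rep(1, 200), bins = 16L)["H_signal"]), 0)

  set.seed(12)
  t <- seq(0, 2, by = 1 / 800)
  h_tone <- entropy_features(sin(2 * pi * 100 * t))["H_freq"]
  h_noise <- entropy_features(rnorm(length(t)))["H_freq"]
  expect_lt(h_tone, h_noise)
})

test_that("MFCCs have length 13, are gain-invariant, and match a brute-force DCT", {
  set.seed(13)
  x <- rnorm(800) / 6
  co <- mfcc_features(x)
  expect_length(co, 13L)
  expect_false(any(!is.finite(co)))

  expect_equal(mfcc_features(5.1 * x), co, tolerance = 1e-9)
  expect_equal(mfcc_features(0.01 * x), co, tolerance = 1e-9)

  expect_error(mfcc_features(x, M = 10L), "M >= L")

  # brute-force oracle on a single fixed frame: naive DFT, naive triangular
  # filters, explicit double-loop DCT (helper-fixtures.R)
  frame <- sin(2 * pi * 90 * (0:31) / 800) + 0.3 * sin(2 * pi * 260 * (0:31) / 800)
  oracle <- mfcc_bruteforce(frame, rate = 800, M = 26, L = 13, nfft = 256)
  got <- mfcc_features(frame, rate = 800, M = 26)
  expect_equal(unname(got), oracle, tolerance = 1e-9)
})

test_that("the full 46-feature vector is finite, named, and gain-invariant", {
  g <- generate_record(healthy_spec(), seed = 21)
  fv <- extract_features(g$record)
  expect_length(fv, 46L)
  expect_identical(names(fv), feature_set_names("C"))
  expect_false(any(!is.finite(fv)))

  half <- audio_record(0.5 * g$record$samples, g$record$rate)
  fv_half <- extract_features(half)
  expect_equal(unclass(fv_half), unclass(fv), tolerance = 1e-6,
               ignore_attr = TRUE)

  expect_length(feature_subset(fv, "A"), 33L)
  expect_length(feature_subset(fv, "B"), 27L)

  # a record with a single pulse cannot yield variability features
  t <- seq(0, 0.12, by = 1 / 800)
  pulse <- exp(-pi * 15 * t) * sin(2 * pi * 80 * t)
  one_beat <- c(numeric(1600), pulse, numeric(1600))
  set.seed(31)
  one_beat <- one_beat + rnorm(length(one_beat)) * 0.002
  rec <- audio_record(one_beat / max(abs(one_beat)), 800)
  expect_error(extract_features(rec), "insufficient beats|no KS")
})
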