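test_that("framing arithmetic matches floor((N - L)/H) + 1", {
  rec <- audio_record(rnorm(800) / 6, 800)
  fr <- frame_signal(rec, 0.040, 0.5)
  expect_equal(fr$L, 32L)
  expect_equal(fr$H, 16L)
  expect_equal(ncol(fr$frames), 49L)        # floor((800-32)/16)+1
  expect_error(frame_signal(audio_record(rnorm(24) / 6, 800), 0.040, 0.5),
               "shorter")
})

test_that("Shannon energy follows the 0 log 0 convention and its oracle value", {
  expect_equal(shannon_energy(numeric(32)), 0)
  expect_equal(shannon_energy(c(1, -1, 1, -1)), 0)     # |z| = 1 -> log 1 = 0
  # direct evaluation: -(1/4) * (0 + 3 * 0.25 * ln 0.25)
  expect_equal(shannon_energy(c(1, 0.5, 0.5, 0.5)),
               -(3 * 0.25 * log(0.25)) / 4, tolerance = 1e-12)
  expect_lt(abs(shannon_energy(c(1, 0.5, 0.5, 0.5)) - 0.2599), 1e-4)
  # scaling the frame leaves the (normalised) energy unchanged
  expect_equal(shannon_energy(c(0.4, 0.2, 0.2, 0.2)),
               shannon_energy(c(1, 0.5, 0.5, 0.5)))
})

test_that("envelope normalisation is an exact z-score with population sd", {
  expect_equal(normalize_envelope(c(0, 2)), c(-1, 1))
  set.seed(2)
  e <- runif(40)
  expect_equal(normalize_envelope(3.7 * e + 1.2), normalize_envelope(e))
  expect_error(normalize_envelope(rep(1, 10)), "degenerate")
  expect_error(normalize_envelope(1), "at least 2")
})

test_that("every constructed envelope has mean 0 and sd 1 and is gain-invariant", {
  for (s in 1:5) {
    g <- generate_record(healthy_spec(noise_snr_db = 15), seed = s)
    env <- shannon_envelope(g$record)
    expect_lt(abs(mean(env$values)), 1e-9)
    expect_lt(abs(sqrt(mean((env$values - mean(env$values))^2)) - 1), 1e-9)
    expect_true(all(diff(env$frame_times) > 0))
    scaled <- audio_record(0.37 * g$record$samples, g$record$rate)
    expect_equal(shannon_envelope(scaled)$values, env$values, tolerance = 1e-9)
  }
})

test_that("anchors are local maxima above the fractional threshold", {
  bump <- function(center, height, width, times) {
    height * pmax(0, 1 - abs(times - center) / width)
  }
  times <- seq(0.02, 6, by = 0.02)
  mk_env <- function(values) {
    structure(list(values = values, frame_times = times,
                   frame_len = 0.04, hop = 0.02), class = "envelope_series")
  }
  one <- mk_env(bump(2, 5, 0.2, times))
  a <- locate_anchors(one, 0.2)
  expect_length(a$times, 1L)
  expect_equal(a$times, 2, tolerance = 0.021)

  # 1 : 0.1 height ratio -> only the taller survives at frac 0.2
  two_small <- mk_env(bump(2, 5, 0.2, times) + bump(4, 0.5, 0.2, times))
  expect_length(locate_anchors(two_small, 0.2)$times, 1L)

  # 1 : 0.5 -> both survive
  two_big <- mk_env(bump(2, 5, 0.2, times) + bump(4, 2.5, 0.2, times))
  expect_length(locate_anchors(two_big, 0.2)$times, 2L)
})

test_that("the merge rule keeps the taller anchor and enforces the gap", {
  a <- structure(list(times = c(1.00, 1.05), heights = c(2, 3)),
                 class = "anchor_set")
  m <- merge_anchors(a, 0.100)
  expect_equal(m$times, 1.05)
  expect_equal(m$heights, 3)

  b <- structure(list(times = c(1.00, 1.15), heights = c(2, 3)),
                 class = "anchor_set")
  expect_length(merge_anchors(b, 0.100)$times, 2L)

  e <- structure(list(times = numeric(0), heights = numeric(0)),
                 class = "anchor_set")
  expect_length(merge_anchors(e, 0.100)$times, 0L)

  # property: surviving pairwise gaps always >= min_gap
  set.seed(4)
  for (i in 1:20) {
    t0 <- sort(runif(30, 0, 10))
    aa <- structure(list(times = t0, heights = runif(30)),
                    class = "anchor_set")
    mm <- merge_anchors(aa, 0.1)
    if (length(mm$times) > 1L) expect_gte(min(diff(mm$times)), 0.1)
  }
})

test_that("artifact rejection drops isolated clicks and keeps regular trains", {
  train <- 5 + 0.8 * (0:14)
  reg <- structure(list(times = train, heights = rep(2, 15)),
                   class = "anchor_set")
  expect_equal(reject_artifacts(reg)$times, train)

  with_click <- structure(list(times = c(0.0, train),
                               heights = c(3, rep(2, 15))),
                          class = "anchor_set")
  expect_equal(reject_artifacts(with_click)$times, train)

  two <- structure(list(times = c(1, 2), heights = c(1, 1)),
                   class = "anchor_set")
  expect_warning(out <- reject_artifacts(two), "fewer than 3")
  expect_equal(out$times, c(1, 2))
})

test_that("record delimiting extends 300/500 ms and clamps to the record", {
  a <- structure(list(times = c(2.0, 20.0), heights = c(1, 1)),
                 class = "anchor_set")
  be <- delimit_record(a, 0.300, 0.500, duration = 25)
  expect_equal(unname(be), c(1.7, 20.5))

  early <- structure(list(times = 0.1, heights = 1), class = "anchor_set")
  expect_equal(unname(delimit_record(early, 0.3, 0.5, 10)[1]), 0)

  none <- structure(list(times = numeric(0), heights = numeric(0)),
                    class = "anchor_set")
  expect_error(delimit_record(none, 0.3, 0.5, 10), "no KS")
})

test_that("beat slicing yields clipped windows and n-1 intervals", {
  rec <- audio_record(rnorm(8000) / 6, 800)
  a <- structure(list(times = c(1.0, 1.8), heights = c(1, 1)),
                 class = "anchor_set")
  seg <- slice_beats(rec, a)
  expect_equal(seg$intervals, 0.8)
  expect_equal(seg$beat_windows[, "start"], c(0.9, 1.7))

  early <- structure(list(times = 0.05, heights = 1), class = "anchor_set")
  expect_equal(unname(slice_beats(rec, early)$beat_windows[1, "start"]), 0)

  many <- structure(list(times = seq(1, by = 0.8, length.out = 12),
                         heights = rep(1, 12)), class = "anchor_set")
  seg12 <- slice_beats(rec, many)
  expect_equal(nrow(seg12$beat_windows), 12L)
  expect_length(seg12$intervals, 11L)
})

test_that("anchors recover ground-truth beats on noisy synthetic records", {
  tot <- c(tp = 0, n_det = 0, n_true = 0)
  for (g in fx_seg50()[1:15]) {
    tot <- tot + match_counts(g$seg$anchors$times, g$beat_times)
  }
  expect_gte(tot["tp"] / tot["n_true"], 0.95)
  expect_gte(tot["tp"] / tot["n_det"], 0.95)
})
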