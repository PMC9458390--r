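## Shannon-energy envelope and KS localisation/segmentation.
##
## The record is cut into 40 ms frames with 50% overlap; each frame's Shannon
## energy -(1/N) sum z^2 log z^2 (z max-normalised within the frame) forms a
## raw envelope, which is z-scored. Anchors (one per Korotkoff sound) are
## envelope local maxima above a fraction of the tallest peak, merged when
## closer than 100 ms, screened for isolated friction artifacts, and the
## record span [B, E] extends 300 ms before the first and 500 ms after the
## last surviving anchor.

#' Cut a record into overlapping frames
#'
#' @param record An [audio_record].
#' @param frame_len Frame length in seconds.
#' @param overlap Fractional overlap in (0, 1).
#' @return List with `frames` (L x n matrix, one frame per column),
#'   `centers` (frame-center times in s), `L`, `H` (frame/hop in samples).
#' @export
frame_signal <- function(record, frame_len = 0.040, overlap = 0.5) {
  L <- round(frame_len * record$rate)
  H <- round(L * (1 - overlap))
  if (L < 2L || H < 1L) stop("degenerate frame geometry")
  N <- length(record$samples)
  if (N < L) stop("record shorter than one frame (", N, " < ", L, " samples)")
  n_frames <- floor((N - L) / H) + 1L
  starts <- (seq_len(n_frames) - 1L) * H
  frames <- vapply(starts,
                   function(s) record$samples[(s + 1L):(s + L)],
                   numeric(L))
  centers <- (starts + (L - 1) / 2) / record$rate
  list(frames = matrix(frames, nrow = L), centers = centers, L = L, H = H)
}

#' Shannon energy of one frame
#'
#' `E = -(1/N) sum z_i^2 log z_i^2` (natural log) with `z_i = x_i / max|x_i|`.
#' Zero samples contribute 0 by the `0 log 0 = 0` convention; an all-zero
#' frame returns 0 and a frame with every `|z_i| = 1` returns 0 (`log 1 = 0`).
#' The Shannon transform emphasises mid-amplitude content over both weak
#' noise and isolated large spikes, which is what makes it a robust pulse
#' envelope.
#'
#' With `normalize = TRUE` (the default) the frame is max-normalised in
#' place. When building an envelope the normalisation must instead be taken
#' over the whole record (one common `max|x|`), otherwise every frame -
#' silence included - is rescaled to unit peak and the envelope loses its
#' amplitude contrast; [shannon_envelope()] therefore normalises the record
#' once and calls this with `normalize = FALSE`.
#'
#' @param frame Numeric vector of amplitudes.
#' @param normalize Max-normalise within the frame (default `TRUE`).
#' @return Non-negative scalar Shannon energy.
#' @export
shannon_energy <- function(frame, normalize = TRUE) {
  if (length(frame) == 0L) stop("empty frame")
  if (normalize) {
    peak <- max(abs(frame))
    if (peak == 0) return(0)
    frame <- frame / peak
  }
  z2 <- frame^2
  nz <- z2 > 0
  -sum(z2[nz] * log(z2[nz])) / length(frame)
}

#' Z-score a raw Shannon-energy series
#'
#' @param raw Numeric vector of per-frame Shannon energies (length >= 2).
#' @return Numeric vector with mean 0 and population standard deviation 1.
#' @export
normalize_envelope <- function(raw) {
  if (length(raw) < 2L) stop("need at least 2 frames")
  mu <- mean(raw)
  sdev <- sqrt(mean((raw - mu)^2))      # population sd: {0,2} -> {-1,1}
  if (sdev == 0) stop("degenerate envelope (constant Shannon energy)")
  (raw - mu) / sdev
}

#' Compute the normalised Shannon-energy envelope of a record
#'
#' @param record An [audio_record].
#' @param config A [run_config()]; supplies frame length and overlap.
#' @return An `envelope_series`: list with `values` (z-scored Shannon energy
#'   per frame), `frame_times` (frame centers, s), `frame_len`, `hop` (s).
#' @export
shannon_envelope <- function(record, config = run_config()) {
  peak <- max(abs(record$samples))
  rec <- if (peak > 0 && peak != 1)
    audio_record(record$samples / peak, record$rate,
                 source_id = record$source_id, label = record$label)
  else record
  fr <- frame_signal(rec, config$frame_len, config$frame_overlap)
  raw <- apply(fr$frames, 2L, shannon_energy, normalize = FALSE)
  structure(list(values = normalize_envelope(raw),
                 frame_times = fr$centers,
                 frame_len = fr$L / record$rate,
                 hop = fr$H / record$rate),
            class = "envelope_series")
}

#' Locate anchor points on an envelope
#'
#' Anchors are strict local maxima of the normalised envelope whose height
#' reaches `threshold_frac` of the tallest peak. Because the envelope is
#' zero-mean, candidates are additionally required to be positive, which
#' keeps the fractional threshold well-posed on near-flat envelopes.
#'
#' @param env An `envelope_series`.
#' @param threshold_frac Fraction of the maximum peak, in (0, 1).
#' @return An `anchor_set`: list with sorted `times` (s) and `heights`.
#' @export
locate_anchors <- function(env, threshold_frac = 0.2) {
  v <- env$values
  n <- length(v)
  if (n < 3L) stop("envelope too short to hold a peak")
  is_peak <- c(FALSE, v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n],
               FALSE)
  thr <- threshold_frac * max(v)
  keep <- is_peak & v >= thr & v > 0
  if (!any(keep))
    warning("no anchors found (monotone or sub-threshold envelope)")
  anchor_set(env$frame_times[keep], v[keep])
}

anchor_set <- function(times, heights) {
  o <- order(times)
  structure(list(times = times[o], heights = heights[o]),
            class = "anchor_set")
}

#' Merge anchors closer than a minimum gap
#'
#' Greedy left-to-right pass: whenever the next anchor lies within `min_gap`
#' of the current cluster's survivor, the two are combined and the taller
#' (larger envelope value) survives. Guarantees all surviving pairs are at
#' least `min_gap` apart.
#'
#' @param anchors An `anchor_set`.
#' @param min_gap Minimum separation in seconds (default 0.100).
#' @return The merged `anchor_set`.
#' @export
merge_anchors <- function(anchors, min_gap = 0.100) {
  n <- length(anchors$times)
  if (n <= 1L) return(anchors)
  keep_t <- anchors$times[1]; keep_h <- anchors$heights[1]
  for (i in 2:n) {
    last <- length(keep_t)
    if (anchors$times[i] - keep_t[last] < min_gap) {
      if (anchors$heights[i] > keep_h[last]) {   # taller pulse survives
        keep_t[last] <- anchors$times[i]
        keep_h[last] <- anchors$heights[i]
      }
    } else {
      keep_t <- c(keep_t, anchors$times[i])
      keep_h <- c(keep_h, anchors$heights[i])
    }
  }
  anchor_set(keep_t, keep_h)
}

#' Reject isolated artifact anchors
#'
#' Friction between the stethoscope diaphragm and the skin produces isolated
#' clicks in the silent phases before and after the KS train. The KS train
#' itself is quasi-periodic, so the longest run of consecutive anchors whose
#' gaps all lie in `[period_min, period_max]` is taken as the true train, and
#' anchors separated from that run by more than `isolation_gap` are dropped.
#'
#' @param anchors A merged `anchor_set`.
#' @param period_min,period_max Admissible inter-beat gap range in seconds
#'   (defaults 0.3 and 2.0).
#' @param isolation_gap Gap beyond which an outside anchor is discarded (s).
#' @return The screened `anchor_set`. Fewer than 3 anchors are returned
#'   unchanged with a warning (no periodicity to test).
#' @export
reject_artifacts <- function(anchors, period_min = 0.3, period_max = 2.0,
                             isolation_gap = 2.0) {
  n <- length(anchors$times)
  if (n < 3L) {
    warning("fewer than 3 anchors; artifact screening skipped")
    return(anchors)
  }
  gaps <- diff(anchors$times)
  ok <- gaps >= period_min & gaps <= period_max
  ## longest run of TRUE gaps -> anchors run_start .. run_end
  best_len <- 0L; best_start <- 1L
  i <- 1L
  while (i <= length(ok)) {
    if (ok[i]) {
      j <- i
      while (j < length(ok) && ok[j + 1L]) j <- j + 1L
      if (j - i + 1L > best_len) { best_len <- j - i + 1L; best_start <- i }
      i <- j + 1L
    } else i <- i + 1L
  }
  if (best_len == 0L) {
    warning("no quasi-periodic anchor run found; anchors returned unchanged")
    return(anchors)
  }
  run_lo <- best_start
  run_hi <- best_start + best_len           # anchor indices of the run
  keep <- rep(FALSE, n)
  keep[run_lo:run_hi] <- TRUE
  ## anchors outside the run survive only if close to it
  for (k in seq_len(n)) {
    if (!keep[k]) {
      d <- min(abs(anchors$times[k] - anchors$times[run_lo:run_hi]))
      if (d <= isolation_gap) keep[k] <- TRUE
    }
  }
  anchor_set(anchors$times[keep], anchors$heights[keep])
}

#' Delimit the KS record span
#'
#' The record begins 300 ms before the first anchor and ends 500 ms after the
#' last, clamped to the recording.
#'
#' @param anchors An `anchor_set` (non-empty).
#' @param pre_extend Seconds before the first anchor (default 0.300).
#' @param post_extend Seconds after the last anchor (default 0.500).
#' @param duration Record duration in seconds.
#' @return Numeric vector `c(B, E)` in seconds.
#' @export
delimit_record <- function(anchors, pre_extend = 0.300, post_extend = 0.500,
                           duration) {
  if (length(anchors$times) == 0L) stop("no KS detected (empty anchor set)")
  c(B = max(0, anchors$times[1] - pre_extend),
    E = min(duration, anchors$times[length(anchors$times)] + post_extend))
}

#' Slice per-beat windows around each anchor
#'
#' @param record An [audio_record].
#' @param anchors An `anchor_set` (non-empty).
#' @param pre,post Window extent around each anchor in seconds
#'   (defaults 0.100 and 0.300).
#' @param pre_extend,post_extend Record-delimiting extents passed through to
#'   [delimit_record()].
#' @return A `record_segmentation`: list with `B`, `E` (s), `anchors`,
#'   `beat_windows` (n x 2 matrix of start/stop times), `intervals`
#'   (successive anchor differences `Ti`, s), `duration`.
#' @export
slice_beats <- function(record, anchors, pre = 0.100, post = 0.300,
                        pre_extend = 0.300, post_extend = 0.500) {
  if (length(anchors$times) == 0L) stop("no KS detected (empty anchor set)")
  dur <- record_duration(record)
  be <- delimit_record(anchors, pre_extend, post_extend, dur)
  win <- cbind(start = pmax(0, anchors$times - pre),
               stop  = pmin(dur, anchors$times + post))
  structure(list(B = unname(be[1]), E = unname(be[2]), anchors = anchors,
                 beat_windows = win, intervals = diff(anchors$times),
                 duration = dur),
            class = "record_segmentation")
}

#' Segment a KS record end to end
#'
#' Envelope, anchor localisation, merging, artifact screening and
#' delimitation in one call. The record is expected to be denoised already
#' (see [denoise_record()]).
#'
#' @param record An [audio_record] at the working rate.
#' @param config A [run_config()].
#' @return A `record_segmentation` (see [slice_beats()]).
#' @export
segment_record <- function(record, config = run_config()) {
  env <- shannon_envelope(record, config)
  a <- locate_anchors(env, config$anchor_threshold_frac)
  a <- merge_anchors(a, config$merge_gap)
  a <- suppressWarnings(reject_artifacts(a))
  slice_beats(record, a, pre = config$beat_pre, post = config$beat_post,
              pre_extend = config$pre_extend, post_extend = config$post_extend)
}

#' @export
print.record_segmentation <- function(x, ...) {
  cat(sprintf("<record_segmentation> %d beats, B=%.2f s, E=%.2f s, mean Ti=%.3f s\n",
              length(x$anchors$times), x$B, x$E,
              if (length(x$intervals)) mean(x$intervals) else NA_real_))
  invisible(x)
}
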