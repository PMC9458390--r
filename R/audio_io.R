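#' Construct an audio record
#'
#' An `audio_record` holds a mono, peak-normalised Korotkoff-sound (KS)
#' waveform together with its sampling rate, a provenance tag and an optional
#' class label. All processing functions in the package take and return this
#' container.
#'
#' @param samples Numeric vector of amplitudes, expected within \[-1, 1\].
#' @param rate Sampling rate in Hz (> 0).
#' @param source_id Free-text provenance tag.
#' @param label Optional class tag: `"healthy"`, `"chf"` or `"unlabeled"`.
#' @return An object of class `audio_record` with fields `samples`, `rate`,
#'   `source_id`, `label`.
#' @export
audio_record <- function(samples, rate, source_id = "unknown",
                         label = c("unlabeled", "healthy", "chf")) {
  label <- match.arg(label)
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop("rate must be a single positive number")
  if (length(samples) == 0L)
    stop("samples must be non-empty")
  if (any(!is.finite(samples)))
    stop("samples must be finite")
  structure(
    list(samples = as.numeric(samples), rate = as.numeric(rate),
         source_id = source_id, label = label),
    class = "audio_record"
  )
}

#' @export
print.audio_record <- function(x, ...) {
  cat(sprintf("<audio_record> %s: %d samples @ %g Hz (%.2f s), label=%s\n",
              x$source_id, length(x$samples), x$rate,
              length(x$samples) / x$rate, x$label))
  invisible(x)
}

#' Duration of an audio record in seconds
#' @param record An `audio_record`.
#' @return Duration in seconds.
#' @export
record_duration <- function(record) length(record$samples) / record$rate

## ---- WAV container --------------------------------------------------------
## Minimal RIFF/WAVE codec for mono PCM16/PCM24 and IEEE float32. Written
## against the RIFF spec; round-trip is exact for float32 and within one
## quantisation step for PCM.

#' Read a mono WAV file
#'
#' Supports PCM 16/24-bit and IEEE float 32-bit encodings. Stereo or
#' multi-channel files are rejected: cuff microphones are single-channel and
#' downmixing would silently change the signal.
#'
#' @param path Path to a `.wav` file.
#' @return List with `samples` (numeric, not yet normalised) and `rate` (Hz).
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAV file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt_raw <- readBin(con, "raw", size)
      fmt <- list(
        audio_format = readBin(fmt_raw[1:2], "integer", 1, 2,
                               signed = FALSE, endian = "little"),
        n_channels   = readBin(fmt_raw[3:4], "integer", 1, 2,
                               signed = FALSE, endian = "little"),
        sample_rate  = readBin(fmt_raw[5:8], "integer", 1, 4,
                               endian = "little"),
        bits         = readBin(fmt_raw[15:16], "integer", 1, 2,
                               signed = FALSE, endian = "little")
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      invisible(readBin(con, "raw", size))
    }
    if (size %% 2L == 1L) invisible(readBin(con, "raw", 1L))  # pad byte
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw))
    stop("malformed WAV (missing fmt or data chunk): ", path)
  if (fmt$n_channels != 1L)
    stop("mono required: file has ", fmt$n_channels, " channels")

  if (fmt$audio_format == 1L && fmt$bits == 16L) {
    x <- readBin(data_raw, "integer", length(data_raw) / 2L, 2,
                 signed = TRUE, endian = "little") / 32768
  } else if (fmt$audio_format == 1L && fmt$bits == 24L) {
    n <- length(data_raw) / 3L
    b <- matrix(as.integer(data_raw), nrow = 3L)
    v <- b[1, ] + 256L * b[2, ] + 65536L * b[3, ]
    v <- ifelse(v >= 8388608, v - 16777216, v)
    x <- v / 8388608
  } else if (fmt$audio_format == 3L && fmt$bits == 32L) {
    x <- readBin(data_raw, "double", length(data_raw) / 4L, 4,
                 endian = "little")
  } else {
    stop("unsupported WAV encoding (format ", fmt$audio_format,
         ", ", fmt$bits, " bit)")
  }
  if (length(x) == 0L) stop("zero-length audio: ", path)
  list(samples = x, rate = fmt$sample_rate)
}

#' Write a mono WAV file
#'
#' @param samples Numeric amplitudes in \[-1, 1\].
#' @param rate Sampling rate in Hz.
#' @param path Output path.
#' @param bits Encoding: 16 (PCM) or 32 (IEEE float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, rate, path, bits = 16L) {
  stopifnot(bits %in% c(16L, 32L))
  n <- length(samples)
  bytes_per <- bits / 8L
  data_size <- n * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(as.integer(if (bits == 16L) 1L else 3L), con, 2, endian = "little")
  writeBin(1L, con, 2, endian = "little")                      # mono
  writeBin(as.integer(rate), con, 4, endian = "little")
  writeBin(as.integer(rate * bytes_per), con, 4, endian = "little")
  writeBin(as.integer(bytes_per), con, 2, endian = "little")
  writeBin(as.integer(bits), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, 4, endian = "little")
  if (bits == 16L) {
    q <- as.integer(round(pmax(pmin(samples, 1), -1) * 32767))
    writeBin(q, con, 2, endian = "little")
  } else {
    writeBin(as.numeric(samples), con, 4, endian = "little")
  }
  invisible(path)
}

#' Load a KS recording from a WAV file
#'
#' Reads a mono WAV file and peak-normalises it so that `max(abs(samples))`
#' equals 1 (all-zero records are left untouched). Peak normalisation at load
#' makes every downstream feature independent of recording gain.
#'
#' @param path Path to a mono WAV file.
#' @param label Optional class tag.
#' @return An [audio_record].
#' @export
load_record <- function(path, label = "unlabeled") {
  w <- read_wav(path)
  peak <- max(abs(w$samples))
  x <- if (peak > 0) w$samples / peak else w$samples
  audio_record(x, w$rate, source_id = basename(path), label = label)
}

#' Resample a record with an anti-aliased polyphase FIR
#'
#' Standard polyphase resampling (via the signal package) to the pipeline's
#' working rate. A call at the record's own rate returns the record unchanged
#' (bitwise), so resampling is idempotent at equal rates.
#'
#' @param record An [audio_record].
#' @param target_rate Target sampling rate in Hz (> 0).
#' @return The resampled [audio_record].
#' @export
resample_record <- function(record, target_rate) {
  if (!is.numeric(target_rate) || length(target_rate) != 1L || target_rate <= 0)
    stop("target_rate must be a single positive number")
  if (target_rate == record$rate) return(record)
  g <- gcd_int(round(target_rate), round(record$rate))
  p <- round(target_rate) / g
  q <- round(record$rate) / g
  y <- signal::resample(record$samples, p, q)
  audio_record(clip_unit(y), target_rate, source_id = record$source_id,
               label = record$label)
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

## resampling FIR ripple can overshoot |1| by a hair; keep the container
## invariant without audibly touching the waveform
clip_unit <- function(x) {
  peak <- max(abs(x))
  if (peak > 1) x / peak else x
}

## ---- run configuration ----------------------------------------------------

#' Pipeline run configuration
#'
#' Bundles every tunable of the processing chain. Defaults reflect the
#' published procedure: 40 ms analysis frames with 50% overlap, an anchor
#' threshold at 0.2 x the maximum envelope peak, a 100 ms anchor merge rule,
#' and 300 ms / 500 ms record delimiting extents. The working rate of 800 Hz
#' is the unique rate at which a 3-level wavelet-packet tree yields eight
#' 50 Hz sub-bands (0-50 ... 350-400 Hz), matching the seven named energy
#' bands above 50 Hz.
#'
#' @param working_rate Working sampling rate in Hz.
#' @param frame_len Analysis frame length in seconds.
#' @param frame_overlap Fractional frame overlap in (0, 1).
#' @param anchor_threshold_frac Anchor threshold as a fraction of the maximum
#'   envelope peak, in (0, 1).
#' @param merge_gap Minimum anchor separation in seconds; closer anchors merge.
#' @param pre_extend Seconds the record start B precedes the first anchor.
#' @param post_extend Seconds the record end E follows the last anchor.
#' @param beat_pre,beat_post Per-beat window extent around each anchor (s).
#' @param wavelet_name Orthogonal wavelet for packet decomposition.
#' @param mfcc_filters Number of triangular Mel filters (>= 13).
#' @param entropy_bins Amplitude-histogram bin count for signal entropy.
#' @param noise_seconds Length of the silent lead-in used for the noise
#'   profile (s).
#' @param rng_seed Integer seed for any stochastic step.
#' @return A list of class `run_config`.
#' @export
run_config <- function(working_rate = 800,
                       frame_len = 0.040,
                       frame_overlap = 0.5,
                       anchor_threshold_frac = 0.2,
                       merge_gap = 0.100,
                       pre_extend = 0.300,
                       post_extend = 0.500,
                       beat_pre = 0.100,
                       beat_post = 0.300,
                       wavelet_name = "db8",
                       mfcc_filters = 26L,
                       entropy_bins = 128L,
                       noise_seconds = 0.5,
                       rng_seed = 1L) {
  cfg <- list(working_rate = working_rate, frame_len = frame_len,
              frame_overlap = frame_overlap,
              anchor_threshold_frac = anchor_threshold_frac,
              merge_gap = merge_gap, pre_extend = pre_extend,
              post_extend = post_extend, beat_pre = beat_pre,
              beat_post = beat_post, wavelet_name = wavelet_name,
              mfcc_filters = as.integer(mfcc_filters),
              entropy_bins = as.integer(entropy_bins),
              noise_seconds = noise_seconds,
              rng_seed = as.integer(rng_seed))
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

validate_run_config <- function(cfg) {
  stopifnot(cfg$working_rate > 0,
            cfg$frame_len > 0,
            cfg$frame_overlap > 0, cfg$frame_overlap < 1,
            cfg$anchor_threshold_frac > 0, cfg$anchor_threshold_frac < 1,
            cfg$merge_gap > 0, cfg$pre_extend > 0, cfg$post_extend > 0,
            cfg$beat_pre > 0, cfg$beat_post > 0,
            cfg$mfcc_filters >= 13L, cfg$entropy_bins >= 2L,
            cfg$noise_seconds > 0)
  invisible(cfg)
}

#' Load a run configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()]; absent keys keep their
#' defaults.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
load_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(run_config, vals)
}
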