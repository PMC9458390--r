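## Synthetic Korotkoff-sound records with ground truth.
##
## A record is a silent lead-in, a train of short damped-oscillation pulses
## whose amplitude rises then falls across the cuff deflation, broadband
## Gaussian noise, and occasional friction clicks in the silent phases. The
## generator targets the signal statistics of cuff-deflation measurements
## (pulse morphology, band energies, beat-interval variability), not the
## underlying hemodynamics.

#' Specification of a synthetic KS record
#'
#' @param n_beats Number of Korotkoff pulses (>= 2).
#' @param mean_period Mean beat period in s (must exceed 4 x the jitter sd).
#' @param period_jitter_sd Standard deviation of the beat period in s.
#' @param pulse_components List of length-3 vectors `c(freq, bandwidth, amp)`:
#'   damped-sinusoid centre frequency (Hz, in (0, 400]), -3 dB bandwidth (Hz,
#'   sets the decay), and relative amplitude.
#' @param amp_peak_frac Position of the loudest beat along the train, as a
#'   fraction of its length (deflation amplitude rises then falls).
#' @param amp_sharpness Sharpness of the rise-fall profile (larger = peakier).
#' @param amp_floor Minimum relative beat amplitude at the train ends.
#' @param en_jitter_sd Lognormal sd of the per-beat amplitude jitter applied
#'   independently to each component; drives beat-to-beat variability of the
#'   low/high-frequency energy ratios.
#' @param noise_snr_db Broadband-noise SNR in dB relative to the pulse-train
#'   power over its active span.
#' @param artifact_rate Expected number of friction clicks per silent phase.
#' @param lead_in,lead_out Silent phases before/after the train, in s.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_beats = 25L,
                           mean_period = 0.8,
                           period_jitter_sd = 0.05,
                           pulse_components = list(c(80, 15, 1.0),
                                                   c(130, 25, 0.55),
                                                   c(250, 60, 0.18)),
                           amp_peak_frac = 0.4,
                           amp_sharpness = 2,
                           amp_floor = 0.35,
                           en_jitter_sd = 0.25,
                           noise_snr_db = 20,
                           artifact_rate = 1,
                           lead_in = 2.0,
                           lead_out = 2.0) {
  stopifnot(n_beats >= 2L, mean_period > 4 * period_jitter_sd,
            length(pulse_components) >= 1L,
            all(vapply(pulse_components, function(pc)
              pc[1] > 0 && pc[1] <= 400 && pc[2] > 0 && pc[3] > 0,
              logical(1))),
            amp_peak_frac > 0, amp_peak_frac < 1, amp_floor >= 0,
            en_jitter_sd >= 0, artifact_rate >= 0,
            lead_in >= 0, lead_out >= 0)
  structure(as.list(environment()), class = "synthetic_spec")
}

#' Healthy-template synthetic spec
#'
#' Impact energy concentrated at 50-100 Hz, a substantial 100-150 Hz
#' component, a small high-frequency murmur, and sizeable beat-to-beat
#' variability of the energy ratios.
#' @param ... Overrides passed to [synthetic_spec()].
#' @return A `synthetic_spec`.
#' @export
healthy_spec <- function(...) {
  args <- list(pulse_components = list(c(80, 15, 1.0), c(130, 25, 0.55),
                                       c(250, 60, 0.18)),
               en_jitter_sd = 0.25)
  do.call(synthetic_spec, utils::modifyList(args, list(...)))
}

#' Reduced-output (CHF-like) synthetic spec
#'
#' Energy shifted away from 100-200 Hz toward the 50-100 Hz band and the
#' bands above 200 Hz, with reduced beat-to-beat variability of the energy
#' ratios - the direction of change observed when cardiac output drops.
#' @param ... Overrides passed to [synthetic_spec()].
#' @return A `synthetic_spec`.
#' @export
chf_spec <- function(...) {
  args <- list(pulse_components = list(c(80, 15, 1.2), c(130, 25, 0.15),
                                       c(250, 60, 0.50)),
               en_jitter_sd = 0.08)
  do.call(synthetic_spec, utils::modifyList(args, list(...)))
}

## run expr with a private RNG stream, restoring the caller's state
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  expr
}

#' Generate one synthetic KS record
#'
#' Each beat is a sum of exponentially damped sinusoids at the spec's
#' components, Gaussian-windowed to under 150 ms; beat times accumulate
#' jittered periods; beat amplitudes follow the rise-fall deflation profile;
#' white Gaussian noise is added at the spec SNR and Poisson-count friction
#' clicks are placed in the silent lead-in/out. Deterministic given `seed`.
#'
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed.
#' @param rate Sampling rate in Hz (default the 800 Hz working rate).
#' @return List with `record` (an [audio_record], peak-normalised),
#'   `beat_times` (ground-truth pulse-energy centroid times, s), `spec`.
#' @export
generate_record <- function(spec, seed = 1L, rate = 800) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_local_seed(seed, {
    periods <- stats::rnorm(spec$n_beats - 1L, spec$mean_period,
                            spec$period_jitter_sd)
    periods <- pmax(periods, 0.30)
    starts <- spec$lead_in + c(0, cumsum(periods))
    duration <- spec$lead_in + sum(periods) + 0.30 + spec$lead_out
    n <- ceiling(duration * rate)
    x <- numeric(n)

    ## rise-then-fall deflation amplitude profile
    u <- if (spec$n_beats > 1L) (seq_len(spec$n_beats) - 1) / (spec$n_beats - 1)
         else 0.5
    a <- spec$amp_sharpness
    shape <- (u^(a * spec$amp_peak_frac) *
              (1 - u)^(a * (1 - spec$amp_peak_frac)))
    shape[!is.finite(shape)] <- 0
    shape <- shape / max(shape)
    amps <- spec$amp_floor + (1 - spec$amp_floor) * shape

    pulse_len <- 0.12
    tp <- seq(0, pulse_len, by = 1 / rate)
    gwin <- exp(-0.5 * ((tp - 0.035) / 0.022)^2)   # < 150 ms support
    truth <- numeric(spec$n_beats)
    for (i in seq_len(spec$n_beats)) {
      p <- numeric(length(tp))
      for (pc in spec$pulse_components) {
        jit <- exp(stats::rnorm(1, 0, spec$en_jitter_sd))
        p <- p + pc[3] * jit * exp(-pi * pc[2] * tp) * sin(2 * pi * pc[1] * tp)
      }
      p <- p * gwin
      ## the component jitter shapes the band-energy mix only; beat loudness
      ## follows the deflation profile
      p <- p / max(abs(p)) * amps[i]
      i0 <- round(starts[i] * rate)
      idx <- i0 + seq_along(tp)
      idx_ok <- idx <= n
      x[idx[idx_ok]] <- x[idx[idx_ok]] + p[idx_ok]
      truth[i] <- (i0 + sum(seq_along(tp) * p^2) / sum(p^2)) / rate
    }

    ## broadband noise at the spec SNR vs active-span pulse power
    active <- (round(starts[1] * rate) + 1L):
      min(n, round((starts[spec$n_beats] + pulse_len) * rate))
    p_sig <- mean(x[active]^2)
    noise_sd <- sqrt(p_sig / 10^(spec$noise_snr_db / 10))
    x <- x + stats::rnorm(n, 0, noise_sd)

    ## friction clicks confined to the silent phases
    click_amp <- 0.8 * max(abs(x))
    for (phase in list(c(0.1, max(0.2, spec$lead_in - 0.5)),
                       c(duration - spec$lead_out + 0.5, duration - 0.1))) {
      if (phase[2] <= phase[1]) next
      n_clicks <- stats::rpois(1, spec$artifact_rate)
      if (n_clicks == 0L) next
      for (tc in stats::runif(n_clicks, phase[1], phase[2])) {
        tcl <- seq(0, 0.012, by = 1 / rate)
        click <- click_amp * exp(-tcl / 0.004) * sin(2 * pi * 180 * tcl)
        idx <- round(tc * rate) + seq_along(tcl)
        idx <- idx[idx >= 1L & idx <= n]
        x[idx] <- x[idx] + click[seq_along(idx)]
      }
    }

    peak <- max(abs(x))
    list(record = audio_record(x / peak, rate,
                               source_id = sprintf("synthetic-%d", seed)),
         beat_times = truth, spec = spec)
  })
}

#' Generate a labelled two-class cohort of synthetic records
#'
#' Draws `n_per_class` records per label. Within-class variance comes from a
#' per-record uniform +/-10% jitter of the continuous spec parameters
#' (period, period jitter, component amplitudes) on top of the per-beat
#' randomness. Passing identical specs for both classes yields a null cohort
#' in which the labels carry no signal.
#'
#' @param n_per_class Records per class (>= 2).
#' @param healthy,patient [synthetic_spec()]s for the two classes.
#' @param seed Integer seed; expands into independent per-record seeds.
#' @param rate Sampling rate in Hz.
#' @return List of `n_per_class * 2` elements, each as returned by
#'   [generate_record()] with the record's `label` set.
#' @export
generate_cohorts <- function(n_per_class, healthy = healthy_spec(),
                             patient = chf_spec(), seed = 1L, rate = 800) {
  if (n_per_class < 2L) stop("need at least 2 records per class")
  n_tot <- 2L * n_per_class
  sub_seeds <- with_local_seed(seed,
    sample.int(.Machine$integer.max - 1L, 2L * n_tot))
  out <- vector("list", n_tot)
  for (i in seq_len(n_tot)) {
    lab <- if (i <= n_per_class) "healthy" else "chf"
    base <- if (lab == "healthy") healthy else patient
    sp <- with_local_seed(sub_seeds[i], jitter_spec(base, 0.10))
    g <- generate_record(sp, seed = sub_seeds[n_tot + i], rate = rate)
    g$record$label <- lab
    g$record$source_id <- sprintf("%s-%03d", lab, i)
    out[[i]] <- g
  }
  out
}

## uniform +/-frac multiplicative jitter of the continuous spec parameters
jitter_spec <- function(spec, frac) {
  j <- function(v) v * stats::runif(length(v), 1 - frac, 1 + frac)
  spec$mean_period <- j(spec$mean_period)
  spec$period_jitter_sd <- j(spec$period_jitter_sd)
  spec$pulse_components <- lapply(spec$pulse_components,
                                  function(pc) c(pc[1], pc[2], j(pc[3])))
  spec$en_jitter_sd <- j(spec$en_jitter_sd)
  validate_spec <- synthetic_spec  # re-run invariant checks
  do.call(validate_spec, spec[names(formals(synthetic_spec))])
}
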