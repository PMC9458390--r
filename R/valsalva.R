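## Before/after Valsalva-maneuver variation analysis of the 19 energy
## features. The Valsalva maneuver transiently reduces venous return and
## cardiac output, so a paired normal-state / maneuver comparison isolates
## the effect of cardiac output on the KS features within one subject.

.valsalva_features <- c("std_enr", "std_enr_h", "std_TM", "std_Ep",
                        "TM_max", "TM_min", "enr_max", "enr_min",
                        "enr_h_max", "enr_h_min", "Ep_max", "Ep_min",
                        "Stotal_50_100", "Stotal_100_150", "Stotal_150_200",
                        "Stotal_200_250", "Stotal_250_300", "Stotal_300_350",
                        "Stotal_350_400")

#' Percent variation between normal state and maneuver
#'
#' `V = (Ns - Vm) / Ns * 100`: positive when the value decreases under the
#' maneuver.
#'
#' @param Ns Value in the normal state (non-zero).
#' @param Vm Value under the Valsalva maneuver.
#' @return Percent variation.
#' @export
variation_percent <- function(Ns, Vm) {
  if (any(Ns == 0)) stop("variation undefined for Ns = 0")
  (Ns - Vm) / Ns * 100
}

#' Before/after variation table for the 19 energy features
#'
#' One row per energy feature, in the conventional reporting order
#' (variability spreads, interval and ratio extrema, then the seven global
#' band ratios), with the normal-state value, the maneuver value and the
#' percent variation.
#'
#' @param features_ns Feature vector (or named numeric) in the normal state.
#' @param features_vm Feature vector under the maneuver.
#' @return Data frame with columns `feature`, `Ns`, `Vm`, `V`.
#' @export
valsalva_table <- function(features_ns, features_vm) {
  ns <- features_ns[.valsalva_features]
  vm <- features_vm[.valsalva_features]
  if (any(is.na(ns)) || any(is.na(vm)))
    stop("feature vectors must contain all 19 energy features")
  zero <- .valsalva_features[ns == 0]
  if (length(zero))
    stop("variation undefined for zero normal-state feature(s): ",
         paste(zero, collapse = ", "))
  data.frame(feature = .valsalva_features,
             Ns = unname(ns), Vm = unname(vm),
             V = unname(variation_percent(ns, vm)),
             row.names = NULL)
}

#' Reference before/after Valsalva measurement pair
#'
#' A published paired measurement of the 19 energy features on one subject
#' in the normal state (`Ns`) and during the Valsalva maneuver (`Vm`),
#' together with the reported percent variation (`V_reported`). Useful as a
#' worked example for [valsalva_table()] and as a numeric check of
#' [variation_percent()]; note that a few reported variations for the very
#' small high-band ratios reflect heavy rounding of `Ns` and do not
#' reproduce exactly from the tabulated values.
#'
#' @return Data frame with columns `feature`, `Ns`, `Vm`, `V_reported`.
#' @export
valsalva_reference <- function() {
  data.frame(
    feature = c("std_enr", "std_enr_h", "std_TM", "std_Ep",
                "TM_max", "TM_min", "enr_max", "enr_min",
                "enr_h_max", "enr_h_min", "Ep_max", "Ep_min",
                "Stotal_50_100", "Stotal_100_150", "Stotal_150_200",
                "Stotal_200_250", "Stotal_250_300", "Stotal_300_350",
                "Stotal_350_400"),
    Ns = c(12.8, 4.99, 19.69, 7.56, 104.43, 94.55, 91.48, 51.37,
           14.05, 0.37, 284.13, 23.92, 75.02, 20.86, 3.56, 0.46,
           0.063, 0.017, 0.014),
    Vm = c(8.89, 3.813, 16.89, 17.81, 103.25, 96.28, 97.76, 69.55,
           13.78, 0.29, 142.24, 23.22, 87.79, 8.47, 1.70, 0.74,
           0.53, 0.47, 0.29),
    V_reported = c(30.71, 23.62, 14.23, -135.53, 1.12, -1.82, -6.87,
                   -35.39, 1.88, 22.70, 49.94, 2.921, -17.02, 59.39,
                   52.24, -60.88, -739.07, -2647.8, -1910.61)
  )
}
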