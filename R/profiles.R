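# Programmed drug-effect profiles for the synthetic transient generator.

#' Drug effect profile for synthetic sessions
#'
#' Per-epoch multipliers applied to the baseline transient rate, plus the
#' lognormal amplitude law. The vehicle epoch multiplier must be 1.
#'
#' @param baseline_rate vehicle-epoch transient rate (events/min).
#' @param multipliers positive per-epoch rate multipliers, one per epoch of
#'   the schedule the profile will be used with; first (vehicle) entry = 1.
#' @param amplitude_mean mean transient amplitude (nM).
#' @param amplitude_cv coefficient of variation of amplitudes.
#' @return an object of class `effect_profile`.
#' @seealso [default_effect_profile()] for the calibrated arm defaults.
#' @export
effect_profile <- function(baseline_rate = 10,
                           multipliers,
                           amplitude_mean = 60,
                           amplitude_cv = 0.4) {
  stop_if_not(baseline_rate > 0, "`baseline_rate` must be positive")
  stop_if_not(length(multipliers) >= 1 && all(is.finite(multipliers)),
              "`multipliers` must be finite")
  stop_if_not(all(multipliers > 0), "all epoch multipliers must be > 0")
  stop_if_not(abs(multipliers[1] - 1) < 1e-12,
              "vehicle epoch multiplier must equal 1")
  stop_if_not(amplitude_mean > 0 && amplitude_cv > 0,
              "amplitude parameters must be positive")
  structure(list(baseline_rate = baseline_rate,
                 multipliers = as.numeric(multipliers),
                 amplitude_mean = amplitude_mean,
                 amplitude_cv = amplitude_cv),
            class = "effect_profile")
}

#' Default per-arm effect profiles
#'
#' Ground-truth rate multipliers for each study arm. Heroin ramps linearly
#' with cumulative dose; buprenorphine is bell-shaped with its peak at the
#' second dose and the two highest doses back near vehicle; in the
#' pretreatment (occlusion) arm the heroin epochs stay near 1. The
#' multiplier values were set by simulation-based calibration of the full
#' generate-extract-detect-summarise chain so that the *detected* group
#' effects land at ~+60% (heroin top dose) and ~+25% (buprenorphine second
#' dose) versus vehicle; detection's refractory merging and thresholding
#' compress observed ratios, so ground-truth multipliers sit slightly above
#' the corresponding observed effect. See the package vignette.
#'
#' @param arm study arm as in [make_dose_schedule()].
#' @inheritParams effect_profile
#' @return an `effect_profile` whose multipliers match the arm's epoch
#'   count (5 for single-drug arms, 9 for `bup_then_heroin`, 1 for
#'   `vehicle_only`).
#' @export
default_effect_profile <- function(arm = c("heroin_alone", "bup_then_heroin",
                                           "vehicle_only"),
                                   baseline_rate = 10,
                                   amplitude_mean = 60,
                                   amplitude_cv = 0.4) {
  arm <- match.arg(arm)
  heroin_ramp <- 1 + (.heroin_top_mult - 1) * c(0.25, 0.5, 0.75, 1)
  bup_bell <- 1 + (.bup_peak_mult - 1) * c(0.45, 1, 0.15, -0.08)
  mult <- switch(arm,
    vehicle_only = 1,
    heroin_alone = c(1, heroin_ramp),
    bup_then_heroin = c(1, bup_bell, rep(.occlusion_mult, 4)))
  effect_profile(baseline_rate = baseline_rate, multipliers = mult,
                 amplitude_mean = amplitude_mean, amplitude_cv = amplitude_cv)
}

# Calibrated ground-truth multipliers (see default_effect_profile and the
# methods vignette for how these were set).
.heroin_top_mult <- 2.30
.bup_peak_mult <- 1.62
.occlusion_mult <- 1.04
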