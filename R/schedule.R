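# Acquisition waveform and cumulative IV dosing schedules.

#' FSCV waveform parameters
#'
#' Triangular scan waveform applied to the carbon-fibre electrode. The
#' defaults are the standard dopamine waveform: -0.4 V to +1.3 V at
#' 400 V/s, repeated every 100 ms (10 scans/s). `samples_per_scan` is the
#' digitizer resolution of one stored voltammogram.
#'
#' @param v_min,v_max holding and switching potentials (V).
#' @param scan_rate sweep rate (V/s).
#' @param scan_period time between scan starts (s); 0.1 s gives 10 Hz.
#' @param samples_per_scan points stored per voltammogram.
#' @return an object of class `waveform_params`.
#' @export
waveform_params <- function(v_min = -0.4, v_max = 1.3, scan_rate = 400,
                            scan_period = 0.1, samples_per_scan = 1000L) {
  stop_if_not(v_max > v_min, "`v_max` must exceed `v_min`")
  stop_if_not(scan_rate > 0, "`scan_rate` must be positive")
  stop_if_not(samples_per_scan >= 2, "`samples_per_scan` must be >= 2")
  dur <- 2 * (v_max - v_min) / scan_rate
  stop_if_not(dur < scan_period,
              "scan sweep duration must fit inside `scan_period`")
  structure(list(v_min = v_min, v_max = v_max, scan_rate = scan_rate,
                 scan_period = scan_period,
                 samples_per_scan = as.integer(samples_per_scan)),
            class = "waveform_params")
}

#' Applied potential axis of one scan
#'
#' Potential at each stored sample of the triangular sweep: first half
#' anodic (`v_min` to `v_max`), second half cathodic back to `v_min`.
#'
#' @param params a [waveform_params()] object.
#' @return numeric vector of length `samples_per_scan` (V).
#' @export
potential_axis <- function(params = waveform_params()) {
  n <- params$samples_per_scan
  half <- n %/% 2
  up <- seq(params$v_min, params$v_max, length.out = half)
  down <- seq(params$v_max, params$v_min, length.out = n - half)
  c(up, down)
}

#' Printed dose ladders
#'
#' Cumulative IV dose ladders (mg/kg) used by the study arms: rat
#' animal-equivalent doses derived from the clinical ascending-dose series
#' (heroin 3.125/6.25/12.5/25 mg per 70 kg; buprenorphine
#' 0.125/0.5/2/8 mg per 70 kg).
#'
#' @name dose_ladders
#' @return numeric vector of cumulative doses (mg/kg).
NULL

#' @rdname dose_ladders
#' @export
heroin_ladder <- function() c(0.27, 0.55, 1.1, 2.2)

#' @rdname dose_ladders
#' @export
bup_ladder <- function() c(0.01, 0.04, 0.18, 0.7)

#' Build a cumulative-dosing schedule
#'
#' One epoch per treatment, `epoch_length_s` apart, always starting with a
#' vehicle (saline) epoch at t = 0. The `bup_then_heroin` arm concatenates
#' the buprenorphine ladder and then the heroin ladder (9 epochs in all);
#' `vehicle_only` is the single vehicle epoch.
#'
#' @param arm one of `"heroin_alone"`, `"bup_then_heroin"`, `"vehicle_only"`.
#' @param dose_ladder increasing cumulative doses (mg/kg) for the arm's
#'   primary drug. For `bup_then_heroin` supply `dose_ladder` for
#'   buprenorphine and `heroin_doses` for the heroin series. Ignored (and
#'   must be empty) for `vehicle_only`.
#' @param epoch_length_s epoch length in seconds (default 600: dosing every
#'   10 minutes).
#' @param heroin_doses heroin ladder for the `bup_then_heroin` arm.
#' @return an object of class `dose_schedule` with an `entries` data frame
#'   (`time_s`, `drug`, `cumulative_dose`) and `epoch_length_s`.
#' @examples
#' make_dose_schedule("heroin_alone", heroin_ladder())
#' @export
make_dose_schedule <- function(arm = c("heroin_alone", "bup_then_heroin",
                                       "vehicle_only"),
                               dose_ladder = NULL,
                               epoch_length_s = 600,
                               heroin_doses = heroin_ladder()) {
  arm <- match.arg(arm)
  stop_if_not(epoch_length_s > 0, "`epoch_length_s` must be positive")
  check_ladder <- function(x, what) {
    stop_if_not(length(x) > 0 && all(x > 0),
                sprintf("%s ladder must be nonempty and positive", what))
    stop_if_not(all(diff(x) > 0),
                sprintf("%s ladder must be strictly increasing", what))
  }
  if (arm == "vehicle_only") {
    stop_if_not(is.null(dose_ladder) || length(dose_ladder) == 0,
                "`vehicle_only` takes no dose ladder")
    entries <- data.frame(time_s = 0, drug = "vehicle", cumulative_dose = 0)
  } else if (arm == "heroin_alone") {
    if (is.null(dose_ladder)) dose_ladder <- heroin_ladder()
    check_ladder(dose_ladder, "heroin")
    entries <- data.frame(
      time_s = epoch_length_s * seq(0, length(dose_ladder)),
      drug = c("vehicle", rep("heroin", length(dose_ladder))),
      cumulative_dose = c(0, dose_ladder))
  } else {
    if (is.null(dose_ladder)) dose_ladder <- bup_ladder()
    check_ladder(dose_ladder, "buprenorphine")
    check_ladder(heroin_doses, "heroin")
    n_b <- length(dose_ladder); n_h <- length(heroin_doses)
    entries <- data.frame(
      time_s = epoch_length_s * seq(0, n_b + n_h),
      drug = c("vehicle", rep("buprenorphine", n_b), rep("heroin", n_h)),
      cumulative_dose = c(0, dose_ladder, heroin_doses))
  }
  structure(list(arm = arm, entries = entries,
                 epoch_length_s = epoch_length_s),
            class = "dose_schedule")
}

#' @export
print.dose_schedule <- function(x, ...) {
  cat(sprintf("<dose_schedule: %s, %d epochs of %g s>\n",
              x$arm, nrow(x$entries), x$epoch_length_s))
  print(x$entries)
  invisible(x)
}

n_epochs <- function(schedule) nrow(schedule$entries)

session_duration <- function(schedule) {
  n_epochs(schedule) * schedule$epoch_length_s
}

#' Assign event times to dose epochs
#'
#' Epochs are half-open `[t_dose, t_dose + epoch_length_s)`; a time exactly
#' on a boundary belongs to the later epoch. Times past the final epoch get
#' `NA`.
#'
#' @param time_s numeric vector of times (s).
#' @param schedule a [make_dose_schedule()] object.
#' @return integer epoch indices (1-based), `NA` outside the session.
#' @export
epoch_of <- function(time_s, schedule) {
  starts <- schedule$entries$time_s
  idx <- findInterval(time_s, starts)
  idx[time_s < starts[1]] <- NA_integer_
  idx[time_s >= starts[length(starts)] + schedule$epoch_length_s] <-
    NA_integer_
  as.integer(idx)
}
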