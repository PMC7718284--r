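# LC-MS standard-curve quantification and a one-compartment cumulative-IV
# plasma simulator.

#' Default LC-MS standard-curve concentration grid (ng/mL)
#'
#' The 12-point calibration series used for buprenorphine, morphine, M3G
#' and 6-AM.
#' @return numeric vector (ng/mL).
#' @export
standard_grid <- function() {
  c(10, 25, 50, 100, 250, 500, 1000, 2500, 5000, 10000, 25000, 50000)
}

#' Fit an LC-MS standard curve
#'
#' Ordinary least-squares line of the analyte/internal-standard response
#' ratio on concentration. The lower limit of quantification (LLOQ) is the
#' lowest grid point.
#'
#' @param concs increasing concentration grid (ng/mL), >= 3 points.
#' @param responses response ratios at each grid point.
#' @param analyte analyte name.
#' @return an object of class `standard_curve`: `slope`, `intercept`,
#'   `R2`, `LLOQ`, grid and responses.
#' @export
fit_standard_curve <- function(concs, responses, analyte = "6AM") {
  stop_if_not(length(concs) >= 3, "need at least 3 calibration points")
  stop_if_not(length(concs) == length(responses), "length mismatch")
  stop_if_not(all(diff(concs) > 0), "`concs` must be strictly increasing")
  fit <- lm.fit(cbind(1, concs), responses)
  rss <- sum(fit$residuals^2)
  tss <- sum((responses - mean(responses))^2)
  structure(list(analyte = analyte,
                 slope = unname(fit$coefficients[2]),
                 intercept = unname(fit$coefficients[1]),
                 R2 = if (tss > 0) 1 - rss / tss else NA_real_,
                 LLOQ = concs[1], grid = concs, responses = responses),
            class = "standard_curve")
}

#' Back-calculate a plasma concentration from a response ratio
#'
#' Inverts the standard curve: `(response - intercept) / slope`. Values
#' below the LLOQ are flagged `below_LLOQ` (summaries report them as
#' LLOQ/2, the flag is retained); negative back-calculations are flagged
#' and clamped to 0 in the summary value.
#'
#' @param curve a [fit_standard_curve()] object.
#' @param response_ratio analyte/internal-standard signal ratio(s).
#' @return data frame: `response_ratio`, `conc_ng_ml` (raw back-calculated
#'   value), `below_LLOQ`, `conc_reported` (summary convention).
#' @export
back_calculate <- function(curve, response_ratio) {
  stop_if_not(inherits(curve, "standard_curve"), "need a `standard_curve`")
  conc <- (response_ratio - curve$intercept) / curve$slope
  below <- conc < curve$LLOQ
  reported <- ifelse(below, curve$LLOQ / 2, conc)
  reported[conc < 0] <- 0
  data.frame(response_ratio = response_ratio, conc_ng_ml = conc,
             below_LLOQ = below, conc_reported = reported)
}

#' One-compartment PK parameters per analyte
#'
#' Invented kinetic defaults for the plasma simulator: 6-AM (heroin's
#' active metabolite) with an 8-minute half-life; buprenorphine with a
#' 5-minute plasma half-life, short enough that 40 minutes after the last
#' buprenorphine dose its concentration has fallen below the 10 ng/mL
#' LLOQ, matching the observed washout. `fraction` is the fraction of the
#' administered parent dose appearing as the analyte.
#'
#' @param vd_l_kg volume of distribution (L/kg).
#' @param half_life_s elimination half-life (s).
#' @param fraction dose-to-analyte conversion fraction.
#' @param source_drug parent drug in the dosing schedule.
#' @return an object of class `pk_params` (list keyed by analyte).
#' @export
pk_params <- function(vd_l_kg = c("6AM" = 2, "buprenorphine" = 1),
                      half_life_s = c("6AM" = 480, "buprenorphine" = 300),
                      fraction = c("6AM" = 0.6, "buprenorphine" = 1),
                      source_drug = c("6AM" = "heroin",
                                      "buprenorphine" = "buprenorphine")) {
  analytes <- names(vd_l_kg)
  stop_if_not(all(vd_l_kg > 0) && all(half_life_s > 0) && all(fraction > 0),
              "all PK parameters must be positive")
  out <- lapply(analytes, function(a) {
    list(analyte = a, vd_l_kg = vd_l_kg[[a]],
         ke = log(2) / half_life_s[[a]], fraction = fraction[[a]],
         source_drug = source_drug[[a]])
  })
  names(out) <- analytes
  structure(out, class = "pk_params")
}

#' Simulate plasma concentrations under cumulative IV dosing
#'
#' Superposition of one-compartment IV boluses: each dose *increment*
#' `dD_i` of an analyte's parent drug contributes
#' `fraction * (dD_i / Vd) * exp(-ke * (t - t_i))` for `t >= t_i`. Units:
#' mg/kg over L/kg = mg/L = ug/mL, scaled to ng/mL. Optional multiplicative
#' lognormal assay noise.
#'
#' @param schedule a [make_dose_schedule()] object.
#' @param params a [pk_params()] object.
#' @param sampling_times sampling times (s) within the session span.
#' @param seed RNG seed for assay noise.
#' @param assay_cv coefficient of variation of the multiplicative assay
#'   noise; 0 gives the noise-free model.
#' @param subject subject id stamped on the samples.
#' @return data frame of class `plasma_samples`: `subject`, `time_s`,
#'   `analyte`, `conc_ng_ml`.
#' @export
simulate_plasma <- function(schedule, params = pk_params(), sampling_times,
                            seed = 1L, assay_cv = 0, subject = 1L) {
  stop_if_not(inherits(schedule, "dose_schedule"), "need a `dose_schedule`")
  stop_if_not(inherits(params, "pk_params"), "need `pk_params`")
  stop_if_not(all(sampling_times >= 0) &&
                all(sampling_times <= session_duration(schedule)),
              "`sampling_times` must lie within the session span")
  ent <- schedule$entries
  out <- list()
  set.seed(as.integer(seed))
  for (a in names(params)) {
    p <- params[[a]]
    rows <- ent[ent$drug == p$source_drug, , drop = FALSE]
    # cumulative doses -> per-epoch increments
    incr <- if (nrow(rows)) diff(c(0, rows$cumulative_dose)) else numeric(0)
    conc <- vapply(sampling_times, function(t) {
      on <- which(rows$time_s <= t)
      if (!length(on)) return(0)
      sum(p$fraction * (incr[on] / p$vd_l_kg) *
            exp(-p$ke * (t - rows$time_s[on])))
    }, numeric(1)) * 1000   # mg/L -> ng/mL
    if (assay_cv > 0) {
      sdlog <- sqrt(log(1 + assay_cv^2))
      conc <- conc * rlnorm(length(conc), -sdlog^2 / 2, sdlog)
    }
    out[[a]] <- data.frame(subject = subject, time_s = sampling_times,
                           analyte = a, conc_ng_ml = conc)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("plasma_samples", "data.frame")
  res
}
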