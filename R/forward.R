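# Forward voltammetric model: analyte templates, background current, and
# rendering of full synthetic scan sessions and chemometric training sets.

#' Unit analyte voltammogram templates
#'
#' Shapes (peak-normalised to 1 nA) of the cyclic-voltammogram signature of
#' each analyte on the dopamine waveform. Dopamine: oxidation feature near
#' +0.6 V on the anodic sweep plus a smaller reduction feature near -0.2 V
#' on the cathodic sweep. The pH template is a broader, clearly distinct
#' basic-shift shape. The two are linearly independent by construction.
#'
#' @param params a [waveform_params()] object.
#' @return list with unit vectors `dopamine` and `ph` (length
#'   `samples_per_scan`).
#' @export
analyte_templates <- function(params = waveform_params()) {
  v <- potential_axis(params)
  n <- length(v)
  anodic <- seq_len(n) <= n %/% 2
  dop <- exp(-(v - 0.6)^2 / (2 * 0.12^2)) * anodic -
    0.35 * exp(-(v + 0.2)^2 / (2 * 0.15^2)) * !anodic
  ph <- -exp(-(v - 0.2)^2 / (2 * 0.35^2)) +
    0.6 * exp(-(v - 1.0)^2 / (2 * 0.25^2))
  list(dopamine = dop / max(abs(dop)), ph = ph / max(abs(ph)))
}

#' Stable non-faradaic background current
#'
#' Capacitive charging-current shape: proportional to the sweep direction
#' with smooth potential-dependent curvature; peak magnitude `magnitude`.
#'
#' @param params a [waveform_params()] object.
#' @param magnitude peak background current (nA).
#' @return numeric vector of length `samples_per_scan` (nA).
#' @export
background_shape <- function(params = waveform_params(), magnitude = 1000) {
  v <- potential_axis(params)
  n <- length(v)
  dir <- c(rep(1, n %/% 2), rep(-1, n - n %/% 2))
  raw <- dir * (0.75 + 0.25 * cos((v - 0.45) * 1.5))
  raw / max(abs(raw)) * magnitude
}

#' Linear molar calibration for dopamine current
#'
#' Maps dopamine oxidation peak current (nA) to concentration (nM):
#' `conc = (slope * current + intercept)`, optionally rescaled by the ratio
#' of the session's observed total background current to a reference value
#' (session-specific calibration: electrode sensitivity tracks background
#' magnitude).
#'
#' @param slope nM per nA; must be positive.
#' @param intercept nM.
#' @param background_ref reference total background current (nA).
#' @param scale_with_background logical; apply the background-proportional
#'   rescaling rule.
#' @return an object of class `calibration_model`.
#' @export
calibration_model <- function(slope = 1, intercept = 0,
                              background_ref = 1000,
                              scale_with_background = TRUE) {
  stop_if_not(slope > 0, "`slope` must be positive")
  stop_if_not(background_ref > 0, "`background_ref` must be positive")
  structure(list(slope = slope, intercept = intercept,
                 background_ref = background_ref,
                 scale_with_background = isTRUE(scale_with_background)),
            class = "calibration_model")
}

# Inverse of current_to_concentration(): dopamine current that the
# electrode would report for a given concentration in a session with the
# stated background magnitude.
conc_to_current <- function(conc_nM, calib, observed_background) {
  scale <- if (calib$scale_with_background) {
    observed_background / calib$background_ref
  } else 1
  (conc_nM / scale - calib$intercept) / calib$slope
}

#' Render a synthetic voltammogram session
#'
#' Forward model: every 100-ms scan is the stable background current plus
#' the dopamine template scaled by the instantaneous dopamine current
#' (through the inverse of the calibration map) plus the pH template scaled
#' by the pH trace, plus iid Gaussian measurement noise. The analysis chain
#' `background_subtract() |> apply_pcr() |> current_to_concentration()`
#' inverts this model.
#'
#' @param conc a [render_concentration()] trace (nM at 10 Hz).
#' @param ph_trace pH-shift trace (a.u.), same length as `conc`; default a
#'   slow low-amplitude oscillation.
#' @param calib a [calibration_model()].
#' @param templates from [analyte_templates()].
#' @param params a [waveform_params()]; `1/scan_period` must equal
#'   `conc$fs`.
#' @param background_nA peak background-current magnitude.
#' @param noise_nA per-sample measurement noise SD.
#' @param seed RNG seed for the measurement noise.
#' @return an object of class `color_plot`: `scans` matrix (n_scans x
#'   samples_per_scan, nA), `time_s`, `potential_v`, plus acquisition
#'   metadata.
#' @export
render_session <- function(conc, ph_trace = NULL,
                           calib = calibration_model(),
                           templates = analyte_templates(params),
                           params = waveform_params(),
                           background_nA = 1000, noise_nA = 0.5,
                           seed = 1L) {
  stop_if_not(inherits(conc, "concentration_trace"),
              "need a `concentration_trace`")
  stop_if_not(abs(1 / params$scan_period - conc$fs) < 1e-9,
              "`conc$fs` must match 1/scan_period")
  tpl <- do.call(cbind, templates)
  stop_if_not(ncol(tpl) >= 2, "need one template per analyte")
  cc <- abs(cor(tpl[, 1], tpl[, 2]))
  stop_if_not(cc < 0.99, "analyte templates are collinear")
  n <- length(conc$time_s)
  if (is.null(ph_trace)) {
    ph_trace <- 0.05 * sin(2 * pi * conc$time_s / 120)
  }
  stop_if_not(length(ph_trace) == n, "`ph_trace` length must match trace")
  bg <- background_shape(params, background_nA)
  cur <- conc_to_current(conc$dopamine_nM, calib, background_nA)
  scans <- tcrossprod(rep(1, n), bg) + tcrossprod(cur, templates$dopamine) +
    tcrossprod(ph_trace, templates$ph)
  if (noise_nA > 0) {
    set.seed(as.integer(seed))
    scans <- scans + rnorm(length(scans), sd = noise_nA)
  }
  structure(list(scans = scans, time_s = conc$time_s,
                 potential_v = potential_axis(params), params = params,
                 background_nA = background_nA, seed = as.integer(seed)),
            class = "color_plot")
}

#' @export
print.color_plot <- function(x, ...) {
  cat(sprintf("<color_plot: %d scans x %d samples (%.1f s at %g Hz)>\n",
              nrow(x$scans), ncol(x$scans), max(x$time_s),
              1 / x$params$scan_period))
  invisible(x)
}

#' @export
plot.color_plot <- function(x, ...) {
  image(x$time_s, seq_along(x$potential_v), x$scans,
        col = hcl.colors(64, "Spectral"), xlab = "time (s)",
        ylab = "sample (sweep order)", ...)
}

#' Render a chemometric training set
#'
#' Seven labelled single-analyte voltammograms per analyte (dopamine in nM,
#' pH in shift units), generated through the same forward model as
#' [render_session()] but background-free, with small measurement noise.
#' Dopamine concentration labels are also stored as current labels (nA)
#' through the calibration inverse so that principal-component regression
#' can be trained in current units.
#'
#' @param templates from [analyte_templates()].
#' @param calib a [calibration_model()].
#' @param concentration_grid list with 7 dopamine levels (nM) and 7 pH
#'   shifts (a.u.).
#' @param seed RNG seed.
#' @param noise_nA exemplar measurement noise SD.
#' @param params a [waveform_params()].
#' @return an object of class `training_set`: exemplar matrix `x`
#'   (14 x samples_per_scan), label matrix `y` (14 x 2: dopamine current
#'   nA, pH shift), and the nM concentration labels.
#' @export
make_training_set <- function(templates = analyte_templates(params),
                              calib = calibration_model(),
                              concentration_grid = list(
                                dopamine = c(50, 100, 200, 400, 600, 800, 1000),
                                ph = c(-0.2, -0.1, -0.05, 0.05, 0.1, 0.15, 0.2)),
                              seed = 1L, noise_nA = 0.5,
                              params = waveform_params()) {
  stop_if_not(length(concentration_grid$dopamine) == 7,
              "need exactly 7 dopamine levels")
  stop_if_not(length(concentration_grid$ph) == 7, "need exactly 7 pH levels")
  stop_if_not(all(concentration_grid$dopamine != 0) &&
                all(concentration_grid$ph != 0),
              "exemplars must not be all-zero")
  cur <- conc_to_current(concentration_grid$dopamine, calib,
                         calib$background_ref)
  x <- rbind(tcrossprod(cur, templates$dopamine),
             tcrossprod(concentration_grid$ph, templates$ph))
  if (noise_nA > 0) {
    set.seed(as.integer(seed))
    x <- x + rnorm(length(x), sd = noise_nA)
  }
  y <- cbind(dopamine_nA = c(cur, rep(0, 7)),
             ph = c(rep(0, 7), concentration_grid$ph))
  structure(list(x = x, y = y,
                 analyte = rep(c("dopamine", "ph"), each = 7),
                 conc_labels = c(concentration_grid$dopamine,
                                 concentration_grid$ph),
                 calib = calib, seed = as.integer(seed)),
            class = "training_set")
}
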