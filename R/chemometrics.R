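# Chemometric extraction: background subtraction, principal-component
# regression, and molar calibration of the dopamine trace.

#' Background-subtract a voltammogram stream
#'
#' Subtracts, within each analysis window, the mean of the window's first
#' `window_scans` consecutive scans (the non-faradaic background estimate).
#' With `window_s = Inf` a single anchor at the start of the recording is
#' used for the whole session.
#'
#' @param plot a `color_plot`.
#' @param window_scans number of consecutive scans averaged as background.
#' @param window_s anchoring window length (s); default one 60-s analysis
#'   window.
#' @return a background-subtracted `color_plot`.
#' @export
background_subtract <- function(plot, window_scans = 10, window_s = 60) {
  stop_if_not(inherits(plot, "color_plot"), "need a `color_plot`")
  n <- nrow(plot$scans)
  stop_if_not(n > window_scans,
              "recording must be longer than the background window")
  fs <- 1 / plot$params$scan_period
  block <- if (is.finite(window_s)) round(window_s * fs) else n
  starts <- seq(1L, n, by = block)
  out <- plot$scans
  for (s in starts) {
    e <- min(s + block - 1L, n)
    anchor <- s:min(s + window_scans - 1L, e)
    out[s:e, ] <- sweep(out[s:e, , drop = FALSE], 2,
                        colMeans(plot$scans[anchor, , drop = FALSE]))
  }
  plot$scans <- out
  plot$background_subtracted <- TRUE
  plot
}

#' Observed total background current of a session
#'
#' Peak magnitude of the mean of the first `window_scans` raw scans; used
#' by the session-specific calibration rule.
#'
#' @inheritParams background_subtract
#' @return scalar background current (nA).
#' @export
observed_background <- function(plot, window_scans = 10) {
  stop_if_not(inherits(plot, "color_plot"), "need a `color_plot`")
  stop_if_not(!isTRUE(plot$background_subtracted),
              "background already subtracted; use the raw session")
  max(abs(colMeans(plot$scans[seq_len(window_scans), , drop = FALSE])))
}

#' Fit a principal-component regression model
#'
#' Singular-value decomposition of the mean-centred training voltammograms;
#' the known analyte labels (dopamine current nA, pH shift) are regressed
#' on the retained component scores by least squares.
#'
#' @param training a [make_training_set()] object.
#' @param k retained components (>= number of analytes, <= 14). If the
#'   training matrix has lower numerical rank, `k` is reduced with a
#'   warning.
#' @param var_target retained components are also required to explain at
#'   least this fraction of training variance; `k` grows if needed.
#' @return an object of class `pcr_model`: orthonormal `basis`
#'   (samples_per_scan x k), regression coefficients, training centre,
#'   explained variance, and training residual variance.
#' @export
build_pcr_model <- function(training, k = 3, var_target = 0.995) {
  stop_if_not(inherits(training, "training_set"), "need a `training_set`")
  stop_if_not(k >= 2, "`k` must retain at least one component per analyte")
  stop_if_not(k <= 14, "`k` cannot exceed the number of exemplars")
  center <- colMeans(training$x)
  xc <- sweep(training$x, 2, center)
  sv <- svd(xc)
  tol <- max(dim(xc)) * .Machine$double.eps * sv$d[1]
  rank <- sum(sv$d > tol)
  if (rank < k) {
    warning(sprintf("training rank %d < k = %d; reducing k", rank, k))
    k <- rank
  }
  cum_var <- cumsum(sv$d^2) / sum(sv$d^2)
  k_var <- which(cum_var >= var_target)[1]
  k <- max(k, min(k_var, rank))
  basis <- sv$v[, seq_len(k), drop = FALSE]
  scores <- xc %*% basis
  fit <- lm.fit(cbind(1, scores), training$y)
  pred <- cbind(1, scores) %*% fit$coefficients
  structure(list(basis = basis, coefficients = fit$coefficients,
                 center = center, k = k,
                 explained_variance = cum_var[k],
                 residual_variance = mean((training$y - pred)^2),
                 calib = training$calib),
            class = "pcr_model")
}

#' Apply a PCR model to a voltammogram stream
#'
#' Projects every (background-subtracted) scan onto the model basis and
#' maps scores to analyte values through the trained regression. The map
#' is linear in the input.
#'
#' @param model a [build_pcr_model()] object.
#' @param plot a background-subtracted `color_plot`.
#' @return an object of class `analyte_traces`: `dopamine_nA` and `ph`
#'   vectors at the scan rate, plus `time_s` and `fs`.
#' @export
apply_pcr <- function(model, plot) {
  stop_if_not(inherits(model, "pcr_model"), "need a `pcr_model`")
  stop_if_not(inherits(plot, "color_plot"), "need a `color_plot`")
  stop_if_not(ncol(plot$scans) == nrow(model$basis),
              "samples_per_scan does not match the PCR model")
  scores <- sweep(plot$scans, 2, model$center) %*% model$basis
  pred <- cbind(1, scores) %*% model$coefficients
  structure(list(dopamine_nA = pred[, 1], ph = pred[, 2],
                 time_s = plot$time_s, fs = 1 / plot$params$scan_period),
            class = "analyte_traces")
}

#' Convert a dopamine current trace to molar concentration
#'
#' `conc = (slope * current + intercept)`, optionally rescaled by
#' `observed_background / background_ref` (session-specific calibration
#' from the observed total background current).
#'
#' @param trace an `analyte_traces` object or a numeric current vector
#'   (nA).
#' @param calib a [calibration_model()].
#' @param observed_background the session's observed total background
#'   current (nA); see [observed_background()].
#' @param fs sampling rate, needed only when `trace` is a bare vector.
#' @return a `concentration_trace` (nM).
#' @export
current_to_concentration <- function(trace, calib = calibration_model(),
                                     observed_background = calib$background_ref,
                                     fs = 10) {
  stop_if_not(inherits(calib, "calibration_model"),
              "need a `calibration_model`")
  stop_if_not(observed_background > 0,
              "`observed_background` must be positive")
  if (inherits(trace, "analyte_traces")) {
    cur <- trace$dopamine_nA
    t <- trace$time_s
    fs <- trace$fs
  } else {
    cur <- as.numeric(trace)
    t <- seq(0, by = 1 / fs, length.out = length(cur))
  }
  scale <- if (calib$scale_with_background) {
    observed_background / calib$background_ref
  } else 1
  structure(list(time_s = t,
                 dopamine_nM = (calib$slope * cur + calib$intercept) * scale,
                 fs = fs),
            class = "concentration_trace")
}
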