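# Transient detection: per-60-s-window dual polynomial fitting (cutoff +
# AIC-selected baseline), 1.5-SD residual thresholding, 0.5-s refractory
# peak merging.

#' Detection parameters
#'
#' @param window_s analysis window length (s); the trace is processed in
#'   independent 60-s files.
#' @param k_sd peak threshold in units of the baseline-residual SD.
#' @param min_sep_s refractory separation: only peaks more than this far
#'   apart are reported; within it, the highest peak wins.
#' @param degree_range candidate polynomial degrees for the baseline line.
#' @param cutoff_degree fixed degree of the peak-threshold ("cutoff") line.
#' @param sd_population which samples enter the residual SD:
#'   `"sub_cutoff"` (samples below the cutoff line) or `"all"`.
#' @param aic_log logarithm base in the AIC: `"natural"` or `"log10"`.
#' @return an object of class `detection_params`.
#' @export
detection_params <- function(window_s = 60, k_sd = 1.5, min_sep_s = 0.5,
                             degree_range = 1:10, cutoff_degree = 2,
                             sd_population = c("sub_cutoff", "all"),
                             aic_log = c("natural", "log10")) {
  stop_if_not(window_s > 0, "`window_s` must be positive")
  stop_if_not(k_sd > 0, "`k_sd` must be positive")
  stop_if_not(min_sep_s > 0, "`min_sep_s` must be positive")
  stop_if_not(length(degree_range) > 0 && all(degree_range >= 0),
              "`degree_range` must be nonempty and nonnegative")
  structure(list(window_s = window_s, k_sd = k_sd, min_sep_s = min_sep_s,
                 degree_range = as.integer(sort(degree_range)),
                 cutoff_degree = as.integer(cutoff_degree),
                 sd_population = match.arg(sd_population),
                 aic_log = match.arg(aic_log)),
            class = "detection_params")
}

#' Akaike information criterion for a least-squares polynomial fit
#'
#' `AIC = n * log(RSS / n) + 2K` with K = number of fitted coefficients.
#' A perfect fit (RSS = 0) returns `-Inf` with a warning.
#'
#' @param n number of points fitted.
#' @param RSS residual sum of squares.
#' @param K number of parameters (degree + 1).
#' @param log_base `"natural"` (default) or `"log10"`.
#' @return AIC score (scalar).
#' @export
aic_score <- function(n, RSS, K, log_base = c("natural", "log10")) {
  log_base <- match.arg(log_base)
  stop_if_not(n > 0, "`n` must be positive")
  stop_if_not(RSS >= 0, "`RSS` must be nonnegative")
  stop_if_not(K >= 0, "`K` must be nonnegative")
  if (RSS == 0) {
    warning("RSS = 0: degenerate perfect fit, AIC = -Inf")
    return(-Inf)
  }
  lg <- if (log_base == "natural") log(RSS / n) else log10(RSS / n)
  n * lg + 2 * K
}

#' Least-squares polynomial fit with AIC
#'
#' Ordinary least squares of `y` on powers of time. Time is internally
#' rescaled to \[-1, 1\] for numerical conditioning; coefficients are
#' reported in the rescaled basis together with the mapping, and
#' [predict.poly_fit()] undoes it.
#'
#' @param t strictly increasing time vector.
#' @param y response vector (same length).
#' @param degree polynomial degree (>= 0).
#' @param log_base AIC logarithm base, see [aic_score()].
#' @return an object of class `poly_fit` with `coefficients` (increasing
#'   power), `degree`, `K`, `n`, `RSS`, `R2`, `AIC`, and the time mapping
#'   `t_range`.
#' @export
fit_poly <- function(t, y, degree, log_base = "natural") {
  stop_if_not(length(t) == length(y), "`t` and `y` lengths differ")
  stop_if_not(length(t) > degree + 1, "underdetermined polynomial fit")
  stop_if_not(all(diff(t) > 0), "`t` must be strictly increasing")
  tr <- range(t)
  xs <- if (diff(tr) > 0) 2 * (t - tr[1]) / diff(tr) - 1 else t * 0
  X <- outer(xs, 0:degree, `^`)
  fit <- lm.fit(X, y)
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) max(0, min(1, 1 - rss / tss)) else as.numeric(rss == 0)
  k <- degree + 1L
  aic <- withCallingHandlers(
    aic_score(length(y), rss, k, log_base),
    warning = function(w) invokeRestart("muffleWarning"))
  structure(list(coefficients = unname(fit$coefficients),
                 degree = as.integer(degree), K = k, n = length(y),
                 RSS = rss, R2 = r2, AIC = aic, t_range = tr,
                 log_base = log_base),
            class = "poly_fit")
}

#' @export
predict.poly_fit <- function(object, t, ...) {
  tr <- object$t_range
  xs <- if (diff(tr) > 0) 2 * (t - tr[1]) / diff(tr) - 1 else t * 0
  drop(outer(xs, 0:object$degree, `^`) %*% object$coefficients)
}

#' @export
print.poly_fit <- function(x, ...) {
  cat(sprintf("<poly_fit: degree %d, n = %d, RSS = %.4g, R2 = %.4f, AIC = %.2f>\n",
              x$degree, x$n, x$RSS, x$R2, x$AIC))
  invisible(x)
}

#' Select the baseline polynomial degree by minimum AIC
#'
#' Fits every degree in `params$degree_range` and returns the fit with the
#' lowest AIC; ties break toward the lower degree. Degrees the window
#' cannot support (too few points) are skipped.
#'
#' @param t,y window time and concentration vectors.
#' @param params a [detection_params()] object.
#' @return the winning `poly_fit`, with the per-degree audit in
#'   `attr(, "candidates")`.
#' @export
select_baseline <- function(t, y, params = detection_params()) {
  degs <- params$degree_range[params$degree_range + 2 <= length(t)]
  stop_if_not(length(degs) > 0,
              "window holds too few points for any candidate degree")
  fits <- lapply(degs, function(d) fit_poly(t, y, d, params$aic_log))
  aics <- vapply(fits, `[[`, numeric(1), "AIC")
  best <- fits[[which.min(aics)]]   # which.min returns the first (lowest
                                    # degree) among exact ties
  audit <- data.frame(degree = degs,
                      RSS = vapply(fits, `[[`, numeric(1), "RSS"),
                      R2 = vapply(fits, `[[`, numeric(1), "R2"),
                      AIC = aics)
  attr(best, "candidates") <- audit
  best
}

#' Detect dopamine transients in a concentration trace
#'
#' Implements the dual-line procedure on independent 60-s windows (a
#' trailing partial window is dropped):
#' \enumerate{
#'   \item fit the fixed-degree "cutoff" polynomial to the whole window by
#'     least squares (the maximal-R2 fit at that degree);
#'   \item fit the "baseline" polynomial, degree chosen by minimum AIC over
#'     `degree_range`, to the samples lying below the cutoff line;
#'   \item form residuals about the baseline; the threshold SD is computed
#'     over the sub-cutoff samples (configurable);
#'   \item local maxima of the residual exceeding `k_sd` SDs (plus a tiny
#'     scale-aware numerical floor for exactly-fitted windows) are
#'     candidate peaks;
#'   \item candidates are greedily merged: the highest remaining candidate
#'     is accepted and all candidates within `min_sep_s` of it are
#'     discarded (equal heights: the earlier apex wins);
#'   \item the reported amplitude is the residual at the apex.
#' }
#'
#' @param trace a `concentration_trace`.
#' @param params a [detection_params()].
#' @param schedule optional [make_dose_schedule()] used to stamp each event
#'   with its dose epoch.
#' @return data frame of class `transient_events`: `time_s`,
#'   `amplitude_nM`, `window_index`, `epoch_index`, plus per-window sigma
#'   in `attr(, "windows")`.
#' @export
detect_transients <- function(trace, params = detection_params(),
                              schedule = NULL) {
  stop_if_not(inherits(trace, "concentration_trace"),
              "need a `concentration_trace`")
  fs <- trace$fs
  wlen <- round(params$window_s * fs)
  n_win <- length(trace$time_s) %/% wlen
  stop_if_not(n_win >= 1, "trace shorter than one analysis window")
  if (length(trace$time_s) %% wlen != 0) {
    warning("trailing partial window dropped")
  }
  ev_t <- numeric(0); ev_a <- numeric(0); ev_w <- integer(0)
  win_audit <- vector("list", n_win)
  for (w in seq_len(n_win)) {
    idx <- ((w - 1L) * wlen + 1L):(w * wlen)
    t <- trace$time_s[idx]; y <- trace$dopamine_nM[idx]
    min_pts <- min(params$degree_range) + 2L
    if (length(t) < max(params$cutoff_degree + 2L, min_pts)) {
      warning(sprintf("window %d too short to fit; skipped", w))
      next
    }
    cutoff <- fit_poly(t, y, params$cutoff_degree, params$aic_log)
    sub <- y < predict(cutoff, t)
    if (sum(sub) < min_pts) {
      warning(sprintf("window %d has too few sub-cutoff samples; skipped", w))
      next
    }
    baseline <- select_baseline(t[sub], y[sub], params)
    resid <- y - predict(baseline, t)
    sigma <- if (params$sd_population == "sub_cutoff") {
      sd(resid[sub])
    } else {
      sd(resid)
    }
    win_audit[[w]] <- list(window_index = w, sigma = sigma,
                           baseline_degree = baseline$degree,
                           baseline = baseline, cutoff = cutoff)
    if (!is.finite(sigma)) next
    m <- length(resid)
    is_max <- c(FALSE, resid[2:(m - 1)] > resid[1:(m - 2)] &
                  resid[2:(m - 1)] >= resid[3:m], FALSE)
    # the additive floor keeps exact-fit (sigma = 0) windows from
    # promoting numerical dust to events
    thr <- params$k_sd * sigma +
      1e-9 * max(diff(range(y)), .Machine$double.eps)
    cand <- which(is_max & resid > thr)
    if (!length(cand)) next
    ord <- cand[order(-resid[cand], t[cand])]
    kept <- numeric(0)
    for (i in ord) {
      if (!length(kept) || all(abs(t[i] - kept) > params$min_sep_s + 1e-9)) {
        kept <- c(kept, t[i])
        ev_t <- c(ev_t, t[i]); ev_a <- c(ev_a, resid[i])
        ev_w <- c(ev_w, w)
      }
    }
  }
  ord <- order(ev_t)
  out <- data.frame(time_s = ev_t[ord], amplitude_nM = ev_a[ord],
                    window_index = ev_w[ord])
  out$epoch_index <- if (!is.null(schedule)) {
    epoch_of(out$time_s, schedule)
  } else NA_integer_
  class(out) <- c("transient_events", "data.frame")
  attr(out, "windows") <- win_audit
  out
}

#' Write the per-window fit audit as JSON
#'
#' Records, for every analysis window, the selected baseline degree, its
#' coefficients, and the RSS/R2/AIC of each candidate degree.
#'
#' @param events a [detect_transients()] result.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_fit_audit <- function(events, path) {
  wins <- Filter(Negate(is.null), attr(events, "windows"))
  audit <- lapply(wins, function(w) {
    list(window_index = w$window_index, sigma = w$sigma,
         baseline_degree = w$baseline_degree,
         baseline_coefficients = w$baseline$coefficients,
         candidates = attr(w$baseline, "candidates"))
  })
  jsonlite::write_json(audit, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
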