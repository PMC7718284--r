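# Synthetic ground truth: Poisson transient trains, drifting baselines,
# and rendered 10 Hz concentration traces.

#' Draw a ground-truth transient train for a session
#'
#' Event times follow a piecewise-homogeneous Poisson process: within each
#' dose epoch the rate is `baseline_rate * multiplier[epoch]`. Amplitudes
#' are lognormal with the profile's mean and CV. A per-60-s-window random
#' cubic drift (zero at each window start) and the trace noise SD are drawn
#' here too, so one `ground_truth` object fully determines a rendered trace.
#'
#' @param schedule a [make_dose_schedule()] object.
#' @param profile an [effect_profile()] with one multiplier per epoch.
#' @param seed integer RNG seed; identical seeds give identical truth.
#' @param noise_sd SD of iid Gaussian trace noise (nM) recorded in the
#'   truth for the renderer.
#' @param drift_coef_sd SD of the random per-window cubic drift
#'   coefficients (nM).
#' @param window_s analysis window length used for drift segmentation (s).
#' @return an object of class `ground_truth`: `events` data frame
#'   (`time_s`, `amplitude_nM`, `epoch_index`), `drift` coefficient matrix
#'   (windows x 3, powers 1..3 on window-local time in \[0,1\]),
#'   `noise_sd`, `rng_seed`, and the schedule/profile used.
#' @export
sample_transients <- function(schedule, profile, seed,
                              noise_sd = 0.5, drift_coef_sd = 5,
                              window_s = 60) {
  stop_if_not(inherits(schedule, "dose_schedule"), "need a `dose_schedule`")
  stop_if_not(inherits(profile, "effect_profile"), "need an `effect_profile`")
  k <- n_epochs(schedule)
  stop_if_not(length(profile$multipliers) == k,
              "profile must define a multiplier for every epoch")
  set.seed(as.integer(seed))
  epoch_min <- schedule$epoch_length_s / 60
  times <- numeric(0); epochs <- integer(0)
  for (i in seq_len(k)) {
    lambda <- profile$baseline_rate * profile$multipliers[i] * epoch_min
    n_i <- rpois(1, lambda)
    if (n_i > 0) {
      t0 <- schedule$entries$time_s[i]
      ti <- sort(runif(n_i, t0, t0 + schedule$epoch_length_s))
      # ties have probability ~0 at double precision; nudge just in case
      while (anyDuplicated(ti)) {
        ti[duplicated(ti)] <- ti[duplicated(ti)] + 1e-9
        ti <- sort(ti)
      }
      times <- c(times, ti)
      epochs <- c(epochs, rep.int(i, n_i))
    }
  }
  sdlog <- sqrt(log(1 + profile$amplitude_cv^2))
  meanlog <- log(profile$amplitude_mean) - sdlog^2 / 2
  amps <- if (length(times)) rlnorm(length(times), meanlog, sdlog) else numeric(0)
  n_win <- ceiling(session_duration(schedule) / window_s)
  drift <- matrix(rnorm(n_win * 3, sd = drift_coef_sd), nrow = n_win,
                  dimnames = list(NULL, c("x1", "x2", "x3")))
  structure(list(
    events = data.frame(time_s = times, amplitude_nM = amps,
                        epoch_index = epochs),
    drift = drift, noise_sd = noise_sd, window_s = window_s,
    rng_seed = as.integer(seed), schedule = schedule, profile = profile),
    class = "ground_truth")
}

#' Transient release kernel
#'
#' Unit-peak bi-exponential kernel: fast rise, slower exponential decay,
#' mimicking sub-second phasic release followed by reuptake.
#'
#' @param t time since event onset (s); values < 0 give 0.
#' @param tau_rise,tau_decay rise and decay time constants (s).
#' @return kernel values, peak normalised to 1.
#' @export
transient_kernel <- function(t, tau_rise = 0.2, tau_decay = 0.7) {
  stop_if_not(tau_decay > tau_rise && tau_rise > 0,
              "need tau_decay > tau_rise > 0")
  t_peak <- log(tau_decay / tau_rise) * tau_rise * tau_decay /
    (tau_decay - tau_rise)
  peak <- exp(-t_peak / tau_decay) - exp(-t_peak / tau_rise)
  h <- ifelse(t < 0, 0, (exp(-t / tau_decay) - exp(-t / tau_rise)) / peak)
  h
}

#' Render a dopamine concentration trace from ground truth
#'
#' Superimposes each event's amplitude-scaled kernel on the per-window
#' polynomial drift and adds iid Gaussian noise of the truth's `noise_sd`.
#' No nonnegativity clipping is applied (noise may dip below the drift).
#'
#' @param truth a [sample_transients()] object.
#' @param fs sampling rate (Hz); 10 Hz matches the 100-ms scan period.
#' @param tau_rise,tau_decay kernel time constants (s).
#' @param noise override the truth's noise SD (nM), e.g. 0 for a noise-free
#'   trace.
#' @return an object of class `concentration_trace`: `time_s`,
#'   `dopamine_nM`, `fs`.
#' @export
render_concentration <- function(truth, fs = 10,
                                 tau_rise = 0.2, tau_decay = 0.7,
                                 noise = NULL) {
  stop_if_not(inherits(truth, "ground_truth"), "need a `ground_truth`")
  dur <- session_duration(truth$schedule)
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  y <- drift_at(truth, t)
  if (nrow(truth$events) > 0) {
    support <- ceiling((tau_decay * 12) * fs)   # kernel negligible beyond
    for (j in seq_len(nrow(truth$events))) {
      t0 <- truth$events$time_s[j]
      i0 <- max(1L, floor(t0 * fs) + 1L)
      i1 <- min(length(t), i0 + support)
      idx <- i0:i1
      y[idx] <- y[idx] + truth$events$amplitude_nM[j] *
        transient_kernel(t[idx] - t0, tau_rise, tau_decay)
    }
  }
  sd_n <- if (is.null(noise)) truth$noise_sd else noise
  if (sd_n > 0) {
    set.seed(child_seed(truth$rng_seed, stage = 101L))
    y <- y + rnorm(length(y), sd = sd_n)
  }
  structure(list(time_s = t, dopamine_nM = y, fs = fs),
            class = "concentration_trace")
}

# Evaluate the per-window drift at arbitrary times. Window-local time is
# rescaled to [0,1]; the drift is zero at each window start.
drift_at <- function(truth, t) {
  w <- pmin(floor(t / truth$window_s) + 1L, nrow(truth$drift))
  x <- (t - (w - 1L) * truth$window_s) / truth$window_s
  truth$drift[w, 1] * x + truth$drift[w, 2] * x^2 + truth$drift[w, 3] * x^3
}

#' @export
print.concentration_trace <- function(x, ...) {
  cat(sprintf("<concentration_trace: %d samples at %g Hz (%.1f s)>\n",
              length(x$time_s), x$fs, length(x$time_s) / x$fs))
  invisible(x)
}

#' @export
plot.concentration_trace <- function(x, ...) {
  plot(x$time_s, x$dopamine_nM, type = "l", xlab = "time (s)",
       ylab = "[DA] (nM)", ...)
}

#' Write a concentration trace or event table to CSV
#'
#' @param x a `concentration_trace` or a data frame of events.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(x, path) {
  if (inherits(x, "concentration_trace")) {
    x <- data.frame(time_s = x$time_s, dopamine_nM = x$dopamine_nM)
  }
  write.csv(x, path, row.names = FALSE)
  invisible(path)
}
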