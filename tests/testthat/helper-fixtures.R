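# Fixture builders and independent oracles shared across the suite.

# Hand-built ground truth with chosen events/drift, bypassing the Poisson
# sampler, so tests control event placement exactly.
make_truth <- function(times, amps, schedule = make_dose_schedule("vehicle_only"),
                       drift = NULL, noise_sd = 0, seed = 1L) {
  n_win <- ceiling(fscvr:::session_duration(schedule) / 60)
  if (is.null(drift)) drift <- matrix(0, n_win, 3)
  structure(list(
    events = data.frame(time_s = times, amplitude_nM = amps,
                        epoch_index = epoch_of(times, schedule)),
    drift = drift, noise_sd = noise_sd, window_s = 60,
    rng_seed = as.integer(seed), schedule = schedule,
    profile = effect_profile(1, rep(1, nrow(schedule$entries)))),
    class = "ground_truth")
}

# Bare concentration trace from a numeric vector.
make_trace <- function(y, fs = 10) {
  structure(list(time_s = seq(0, by = 1 / fs, length.out = length(y)),
                 dopamine_nM = y, fs = fs),
            class = "concentration_trace")
}

# Time offset from event onset to kernel apex.
kernel_apex_offset <- function(tau_rise = 0.2, tau_decay = 0.7) {
  log(tau_decay / tau_rise) * tau_rise * tau_decay / (tau_decay - tau_rise)
}

# Match detected apex times against true apex times within a tolerance;
# returns recall and precision. Greedy one-to-one matching.
match_events <- function(detected, truth_onsets, tol = 0.2) {
  apex <- truth_onsets + kernel_apex_offset()
  used <- rep(FALSE, length(apex))
  hits <- 0L
  for (td in detected) {
    d <- abs(apex - td)
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) && d[j] <= tol) {
      used[j] <- TRUE
      hits <- hits + 1L
    }
  }
  list(recall = if (length(apex)) hits / length(apex) else NA_real_,
       precision = if (length(detected)) hits / length(detected) else NA_real_)
}

# Brute-force baseline-degree oracle: fit every degree with stats::lm on
# an orthogonal-free raw polynomial basis and take the AIC argmin
# (first minimum = lowest degree on ties).
oracle_baseline_degree <- function(t, y, degrees = 1:10) {
  ts <- 2 * (t - min(t)) / diff(range(t)) - 1
  aics <- vapply(degrees, function(d) {
    fit <- stats::lm(y ~ stats::poly(ts, d, raw = TRUE))
    rss <- sum(stats::residuals(fit)^2)
    if (rss == 0) return(-Inf)
    length(y) * log(rss / length(y)) + 2 * (d + 1)
  }, numeric(1))
  degrees[which.min(aics)]
}

# Textbook one-way repeated-measures ANOVA sums of squares (wide matrix:
# subjects x conditions); returns F, df1, df2.
oracle_rm_anova <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  ss_cond <- n * sum((colMeans(m) - grand)^2)
  ss_subj <- k * sum((rowMeans(m) - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- k - 1; df2 <- (n - 1) * (k - 1)
  list(F = (ss_cond / df1) / (ss_err / df2), df1 = df1, df2 = df2)
}

# Explicit-rank Kruskal-Wallis H (no tie correction needed for distinct
# values).
oracle_kruskal_h <- function(groups) {
  y <- unlist(groups)
  r <- rank(y)
  n <- length(y)
  idx <- rep(seq_along(groups), lengths(groups))
  rbar <- tapply(r, idx, mean)
  ni <- lengths(groups)
  12 / (n * (n + 1)) * sum(ni * (rbar - (n + 1) / 2)^2)
}
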