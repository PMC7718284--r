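test_that("polynomial fits are exact on polynomial data and nested in RSS", {
  t <- seq(0, 59.9, by = 0.1)
  f0 <- fit_poly(t, rep(3, length(t)), 0)
  expect_equal(f0$coefficients, 3)
  expect_equal(f0$RSS, 0)

  y <- 2 * t^2 + 3
  f2 <- fit_poly(t, y, 2)
  expect_lt(f2$RSS, 1e-12)
  expect_equal(predict(f2, t), y, tolerance = 1e-9)
  expect_equal(f2$R2, 1)

  set.seed(5)
  yn <- y + rnorm(length(t))
  rss <- vapply(0:6, function(d) fit_poly(t, yn, d)$RSS, numeric(1))
  expect_true(all(diff(rss) <= 1e-8))   # nested least squares

  expect_error(fit_poly(t[1:3], yn[1:3], 5), "underdetermined")
  expect_error(fit_poly(rev(t), yn, 2), "increasing")
})

test_that("the AIC formula matches direct evaluation", {
  expect_equal(aic_score(600, 600, 3), 6)
  expect_equal(aic_score(100, 100 * exp(1), 0), 100)
  expect_equal(aic_score(600, 60, 4), 600 * log(60 / 600) + 2 * 4)
  expect_equal(aic_score(600, 60, 4, "log10"), 600 * log10(0.1) + 8)
  expect_warning(val <- aic_score(10, 0, 2), "degenerate")
  expect_identical(val, -Inf)
})

test_that("baseline degree selection equals the brute-force AIC argmin", {
  t <- seq(0, 60, length.out = 121)
  params <- detection_params()

  # noiseless cubic window -> degree 3 (perfect fits above are -Inf ties;
  # tie goes to the lowest degree achieving it)
  y3 <- 1 + 0.5 * t - 0.02 * t^2 + 3e-4 * t^3
  expect_equal(suppressWarnings(select_baseline(t, y3, params))$degree, 3)

  # constant + tiny noise -> degree 1 (no RSS gain offsets +2 per K)
  set.seed(11)
  yc <- 5 + rnorm(length(t), sd = 0.01)
  expect_equal(select_baseline(t, yc, params)$degree, 1)

  # randomized windows agree with the independent lm-based oracle
  set.seed(99)
  for (i in 1:200) {
    d_true <- sample(1:5, 1)
    y <- drop(outer(t / 60, 0:d_true, `^`) %*% rnorm(d_true + 1, sd = 2)) +
      rnorm(length(t), sd = 0.5)
    got <- select_baseline(t, y, params)$degree
    expect_equal(got, oracle_baseline_degree(t, y))
  }
})

test_that("detection finds isolated bumps and honours the threshold", {
  bump_at <- function(y, i, height) {
    k <- transient_kernel(seq(0, 5, by = 0.1))
    j <- i:(i + length(k) - 1)
    y[j] <- y[j] + height * k
    y
  }
  apex_k <- which.max(transient_kernel(seq(0, 5, by = 0.1)))

  # flat noise-free window + one 50-nM bump -> exactly one event, at the
  # apex sample, with the injected amplitude
  y1 <- bump_at(rep(0, 600), 300, 50)
  ev1 <- detect_transients(make_trace(y1))
  expect_equal(nrow(ev1), 1)
  expect_lt(abs(ev1$time_s - (299 + apex_k - 1) / 10), 0.2)
  expect_equal(ev1$amplitude_nM, 50, tolerance = 0.05)
  sigma1 <- attr(ev1, "windows")[[1]]$sigma
  expect_gt(ev1$amplitude_nM, 1.5 * sigma1)

  # a second bump whose apex residual is only 1.2 SD stays undetected
  y2 <- bump_at(y1, 100, 1.2 * sigma1)
  ev2 <- detect_transients(make_trace(y2))
  expect_equal(nrow(ev2), 1)
  expect_lt(abs(ev2$time_s - (299 + apex_k - 1) / 10), 0.2)
})

test_that("refractory merging keeps the tallest peak within 0.5 s", {
  # two bumps 0.3 s apart, second taller -> single event at the taller apex
  tr <- render_concentration(
    make_truth(c(20, 20.3), c(40, 60),
               make_dose_schedule("vehicle_only", epoch_length_s = 60)))
  ev <- detect_transients(tr)
  expect_equal(nrow(ev), 1)
  expect_lt(abs(ev$time_s - (20.3 + kernel_apex_offset())), 0.25)

  # two equal bumps 1.0 s apart -> both reported
  tr2 <- render_concentration(
    make_truth(c(20, 21), c(60, 60),
               make_dose_schedule("vehicle_only", epoch_length_s = 60)))
  ev2 <- detect_transients(tr2)
  expect_equal(nrow(ev2), 2)
})

test_that("noise-free separable events give recall = precision = 1", {
  sched <- make_dose_schedule("vehicle_only")
  set.seed(31)
  onsets <- sort(5 + cumsum(runif(40, 8, 18)))
  onsets <- onsets[onsets < 590]
  # keep apexes clear of 60-s window seams: windows are independent and a
  # peak on the boundary sample cannot be a local maximum of either window
  onsets <- onsets[abs((onsets + kernel_apex_offset()) %% 60) > 1 &
                     abs((onsets + kernel_apex_offset()) %% 60) < 59]
  truth <- make_truth(onsets, runif(length(onsets), 30, 90), sched,
                      drift = matrix(rnorm(30, sd = 5), 10, 3))
  ev <- detect_transients(render_concentration(truth), schedule = sched)
  m <- match_events(ev$time_s, onsets, tol = 0.2)
  expect_equal(m$recall, 1)
  expect_equal(m$precision, 1)
})

test_that("every reported event pair is separated by more than 0.5 s", {
  sched <- make_dose_schedule("vehicle_only")
  prof <- default_effect_profile("vehicle_only", baseline_rate = 15)
  for (sd in 1:20) {
    truth <- sample_transients(sched, prof, seed = 300 + sd)
    ev <- detect_transients(render_concentration(truth), schedule = sched)
    if (nrow(ev) > 1) expect_gt(min(diff(ev$time_s)), 0.5)
    # all amplitudes exceed the window threshold
    wins <- attr(ev, "windows")
    sig <- vapply(wins, function(w) w$sigma, numeric(1))
    expect_true(all(ev$amplitude_nM > 1.5 * sig[ev$window_index]))
  }
})

test_that("default-session detection meets recall/false-positive regression", {
  sched <- make_dose_schedule("vehicle_only")
  prof <- default_effect_profile("vehicle_only")
  rec <- fp <- numeric(100)
  for (i in 1:100) {
    truth <- sample_transients(sched, prof, seed = 400 + i)
    ev <- detect_transients(render_concentration(truth), schedule = sched)
    apex <- truth$events$time_s + kernel_apex_offset()
    big <- apex[truth$events$amplitude_nM >= 40]
    # recall: true >= 40 nM events recovered by any detection;
    # false positives: >= 40 nM detections matching no true event at all
    hit <- vapply(big, function(a) any(abs(ev$time_s - a) <= 0.3),
                  logical(1))
    det_big <- ev$time_s[ev$amplitude_nM >= 40]
    spurious <- vapply(det_big,
                       function(d) all(abs(apex - d) > 0.3), logical(1))
    rec[i] <- mean(hit)
    fp[i] <- sum(spurious) / 10
  }
  expect_gte(mean(rec, na.rm = TRUE), 0.9)
  expect_lte(mean(fp), 0.1)   # false positives >= 40 nM per minute
})

test_that("short traces and partial windows are handled explicitly", {
  expect_error(detect_transients(make_trace(rnorm(100))), "shorter")
  expect_warning(detect_transients(make_trace(c(rnorm(650)))), "partial")
})
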