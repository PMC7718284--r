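wf <- waveform_params(samples_per_scan = 200)   # small scans: fast tests
tpl <- analyte_templates(wf)
calib <- calibration_model()

# short noise-free session around two mid-window events
sched1 <- make_dose_schedule("vehicle_only", epoch_length_s = 120)
truth1 <- make_truth(c(25, 80), c(60, 40), sched1)
conc1 <- render_concentration(truth1)

test_that("background subtraction removes the anchor-block mean", {
  zero <- make_trace(rep(0, 300))
  sess <- render_session(zero, ph_trace = rep(0, 300), calib = calib,
                         templates = tpl, params = wf, noise_nA = 0)
  sub <- background_subtract(sess, window_s = Inf)
  expect_equal(max(abs(sub$scans)), 0, tolerance = 1e-10)

  # step increase after the anchor: zero before, step height after
  stepped <- sess
  stepped$scans[151:300, ] <- stepped$scans[151:300, ] + 5
  sub2 <- background_subtract(stepped, window_s = Inf)
  expect_equal(max(abs(sub2$scans[1:150, ])), 0, tolerance = 1e-10)
  expect_true(all(abs(sub2$scans[151:300, ] - 5) < 1e-8))

  short <- sess; short$scans <- sess$scans[1:5, ]
  expect_error(background_subtract(short), "longer")
})

test_that("PCR training reproduces labels and scales linearly", {
  # noiseless training from the two templates: exact at machine precision
  ts0 <- make_training_set(tpl, calib, seed = 1, noise_nA = 0, params = wf)
  m0 <- suppressWarnings(build_pcr_model(ts0, k = 3))
  expect_lte(m0$k, 2)   # rank-deficient noiseless set reduces k
  scores <- sweep(ts0$x, 2, m0$center) %*% m0$basis
  pred <- cbind(1, scores) %*% m0$coefficients
  expect_equal(pred, ts0$y, tolerance = 1e-9, ignore_attr = TRUE)

  # labels scaled x2 -> coefficients scaled x2
  ts2 <- ts0; ts2$y <- 2 * ts0$y
  m2 <- suppressWarnings(build_pcr_model(ts2, k = 2))
  expect_equal(m2$coefficients, 2 * m0$coefficients, tolerance = 1e-9)

  # 1% relative noise: label reconstruction R2 > 0.99
  tsn <- make_training_set(tpl, calib, seed = 7, noise_nA = 0.5, params = wf)
  mn <- build_pcr_model(tsn, k = 3)
  scn <- sweep(tsn$x, 2, mn$center) %*% mn$basis
  prn <- cbind(1, scn) %*% mn$coefficients
  r2 <- 1 - sum((prn[, 1] - tsn$y[, 1])^2) /
    sum((tsn$y[, 1] - mean(tsn$y[, 1]))^2)
  expect_gt(r2, 0.99)

  expect_error(build_pcr_model(tsn, k = 1), "at least")
  expect_warning(build_pcr_model(ts0, k = 3), "reducing k")

  # basis orthonormality: Gram matrix = identity
  expect_equal(crossprod(mn$basis), diag(mn$k), tolerance = 1e-8)
})

test_that("apply_pcr is linear and separates the analytes", {
  ts <- make_training_set(tpl, calib, seed = 3, noise_nA = 0, params = wf)
  m <- suppressWarnings(build_pcr_model(ts, k = 2))
  mk_plot <- function(scans) {
    structure(list(scans = scans, time_s = seq_len(nrow(scans)) / 10,
                   potential_v = potential_axis(wf), params = wf),
              class = "color_plot")
  }
  x <- mk_plot(tcrossprod(c(10, 20, 30), tpl$dopamine))
  y <- mk_plot(tcrossprod(c(0.1, 0.2, 0.3), tpl$ph))
  ax <- apply_pcr(m, x); ay <- apply_pcr(m, y)
  expect_equal(ax$dopamine_nA, c(10, 20, 30), tolerance = 1e-8)
  expect_equal(max(abs(ax$ph)), 0, tolerance = 1e-8)
  expect_equal(ay$ph, c(0.1, 0.2, 0.3), tolerance = 1e-8)
  expect_equal(max(abs(ay$dopamine_nA)), 0, tolerance = 1e-6)

  comb <- mk_plot(2 * x$scans + 0.5 * y$scans)
  ac <- apply_pcr(m, comb)
  expect_equal(ac$dopamine_nA, 2 * ax$dopamine_nA + 0.5 * ay$dopamine_nA,
               tolerance = 1e-9)
  zero <- apply_pcr(m, mk_plot(matrix(0, 3, wf$samples_per_scan)))
  expect_equal(zero$dopamine_nA, rep(0, 3), tolerance = 1e-9)

  bad <- mk_plot(matrix(0, 3, 50))
  expect_error(apply_pcr(m, bad), "match")
})

test_that("molar calibration applies the background-proportional rule", {
  cal <- calibration_model(slope = 1, intercept = 0, background_ref = 1000)
  cur <- c(0, 10, 50)
  expect_equal(current_to_concentration(cur, cal, 1000)$dopamine_nM, cur)
  expect_equal(current_to_concentration(cur, cal, 2000)$dopamine_nM, 2 * cur)
  off <- calibration_model(scale_with_background = FALSE)
  expect_equal(current_to_concentration(cur, off, 2000)$dopamine_nM, cur)
  expect_error(current_to_concentration(cur, cal, -5), "positive")
})

test_that("the full forward/inverse chain recovers concentration to <1%", {
  sess <- render_session(conc1, calib = calib, templates = tpl, params = wf,
                         noise_nA = 0)
  bg <- observed_background(sess)
  expect_equal(bg, 1000, tolerance = 1e-6)
  rec <- current_to_concentration(apply_pcr(
    suppressWarnings(build_pcr_model(
      make_training_set(tpl, calib, seed = 1, noise_nA = 0, params = wf),
      k = 2)),
    background_subtract(sess)), calib, bg)
  err <- max(abs(rec$dopamine_nM - conc1$dopamine_nM))
  expect_lt(err / max(conc1$dopamine_nM), 0.01)
})

test_that("doubling concentration doubles the dopamine coefficient per scan", {
  conc2 <- conc1
  conc2$dopamine_nM <- 2 * conc1$dopamine_nM
  s1 <- render_session(conc1, ph_trace = rep(0, 1200), calib = calib,
                       templates = tpl, params = wf, noise_nA = 0)
  s2 <- render_session(conc2, ph_trace = rep(0, 1200), calib = calib,
                       templates = tpl, params = wf, noise_nA = 0)
  bgm <- background_shape(wf, 1000)
  coef1 <- (s1$scans - tcrossprod(rep(1, 1200), bgm)) %*% tpl$dopamine /
    sum(tpl$dopamine^2)
  coef2 <- (s2$scans - tcrossprod(rep(1, 1200), bgm)) %*% tpl$dopamine /
    sum(tpl$dopamine^2)
  expect_equal(coef2, 2 * coef1, tolerance = 1e-9)
})

test_that("collinear templates are rejected", {
  bad <- list(dopamine = tpl$dopamine, ph = tpl$dopamine * 0.5)
  expect_error(render_session(conc1, calib = calib, templates = bad,
                              params = wf),
               "collinear")
})

test_that("training sets are deterministic under a fixed seed", {
  a <- make_training_set(tpl, calib, seed = 9, params = wf)
  b <- make_training_set(tpl, calib, seed = 9, params = wf)
  expect_identical(a, b)
  expect_error(make_training_set(tpl, calib,
    concentration_grid = list(dopamine = 1:5, ph = 1:7), params = wf),
    "7 dopamine")
})
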