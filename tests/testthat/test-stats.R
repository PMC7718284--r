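test_that("the distribution gate branches on normality and variance", {
  set.seed(101)
  # well-behaved normal cells -> parametric
  g_norm <- replicate(4, rnorm(30), simplify = FALSE)
  expect_equal(distribution_gate(g_norm)$branch, "parametric")

  # heavy lognormal cells reject normality in most draws
  hits <- vapply(1:50, function(i) {
    set.seed(200 + i)
    g <- replicate(3, rlnorm(20, 0, 1.5), simplify = FALSE)
    distribution_gate(g)$branch == "nonparametric"
  }, logical(1))
  expect_gt(mean(hits), 0.9)

  # degenerate constant cells force the nonparametric branch
  expect_warning(d <- distribution_gate(list(rep(1, 5), rep(1, 5))),
                 "degenerate")
  expect_equal(d$branch, "nonparametric")
  expect_warning(s <- distribution_gate(list(1:2, rnorm(5))), "n < 3")
  expect_equal(s$branch, "nonparametric")
})

test_that("repeated-measures F matches the hand-computed sum-of-squares oracle", {
  m <- matrix(c(3.1, 4.0, 5.2,
                2.8, 4.4, 5.9,
                3.5, 3.9, 6.1), nrow = 3, byrow = TRUE)
  design <- data.frame(subject = rep(1:3, each = 3),
                       epoch = rep(1:3, times = 3),
                       value = as.vector(t(m)))
  res <- omnibus_and_posthoc(design, "parametric")
  oracle <- oracle_rm_anova(m)
  expect_equal(unname(res$statistic), oracle$F, tolerance = 1e-10)
  expect_equal(unname(res$df), c(oracle$df1, oracle$df2))
  expect_match(res$label, "F\\(2,4\\)")
  expect_true(all(c("comparison", "p_adj", "significant") %in%
                    names(res$posthoc)))
})

test_that("identical epoch distributions give F near 0 and p near 1", {
  # every epoch holds the same set of values (rows are cyclic shifts), so
  # epoch means are identical while residual variance is nonzero
  design <- data.frame(subject = rep(1:3, each = 3),
                       epoch = rep(1:3, times = 3),
                       value = c(1, 2, 3, 2, 3, 1, 3, 1, 2))
  res <- omnibus_and_posthoc(design, "parametric", posthoc = FALSE)
  expect_lt(unname(res$statistic), 1e-10)
  expect_gt(res$p, 0.999)
})

test_that("Kruskal-Wallis H matches the explicit rank formula", {
  groups <- list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9))
  design <- data.frame(subject = rep(1:3, 3),
                       epoch = rep(1:3, each = 3),
                       value = unlist(groups))
  res <- omnibus_and_posthoc(design, "nonparametric")
  expect_equal(unname(res$statistic), oracle_kruskal_h(groups),
               tolerance = 1e-12)
  expect_equal(unname(res$statistic), 7.2)
  expect_match(res$label, "H\\(2\\)")
  expect_equal(nrow(res$posthoc), 3)   # Dunn pairwise with Holm adjustment
})

test_that("F and H are invariant to shifts; F to positive rescaling", {
  set.seed(303)
  design <- data.frame(subject = rep(1:5, each = 4),
                       epoch = rep(1:4, times = 5),
                       value = rnorm(20))
  f0 <- omnibus_and_posthoc(design, "parametric", posthoc = FALSE)
  h0 <- omnibus_and_posthoc(design, "nonparametric", posthoc = FALSE)
  d1 <- design; d1$value <- d1$value + 100
  d2 <- design; d2$value <- d2$value * 7.5
  expect_equal(omnibus_and_posthoc(d1, "parametric", posthoc = FALSE)$statistic,
               f0$statistic, tolerance = 1e-9)
  expect_equal(omnibus_and_posthoc(d2, "parametric", posthoc = FALSE)$statistic,
               f0$statistic, tolerance = 1e-9)
  expect_equal(omnibus_and_posthoc(d1, "nonparametric", posthoc = FALSE)$statistic,
               h0$statistic, tolerance = 1e-12)
})

test_that("incomplete subjects are excluded listwise with a warning", {
  design <- data.frame(subject = c(rep(1:3, each = 3), 4),
                       epoch = c(rep(1:3, times = 3), 1),
                       value = rnorm(10))
  expect_warning(res <- omnibus_and_posthoc(design, "parametric",
                                            posthoc = FALSE),
                 "listwise")
  expect_equal(unname(res$df[2]), 4)   # 3 complete subjects remain
})

test_that("the mixed two-way design reports the arm-by-epoch interaction", {
  set.seed(404)
  design <- expand.grid(subject = 1:8, epoch = 1:3)
  design$arm <- ifelse(design$subject <= 4, "heroin", "bup")
  design$value <- rnorm(nrow(design)) +
    ifelse(design$arm == "heroin", design$epoch * 0.5, 0)
  design$subject <- paste0(design$arm, design$subject)
  res <- omnibus_and_posthoc(design, "parametric", posthoc = FALSE)
  expect_equal(unname(res$df), c(2, 12))   # (a-1)(e-1), (n-2)(e-1)
  expect_true(is.finite(res$p))
})
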