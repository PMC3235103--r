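test_that("Welch t matches the reference implementation to 1e-10", {
  x <- c(1, 2, 3)
  y <- c(1, 2, 3, 4, 5, 6)
  ours <- welch_t(x, y)
  ref <- stats::t.test(x, y)
  expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(ours$df, unname(ref$parameter), tolerance = 1e-10)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
  set.seed(91)
  for (i in 1:10) {
    a <- rnorm(sample(3:20, 1), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(3:20, 1), mean = runif(1, -1, 1))
    ours <- welch_t(a, b)
    ref <- stats::t.test(a, b)
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$df, unname(ref$parameter), tolerance = 1e-10)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("Welch t handles ties, tails, and degenerate variances", {
  x <- c(1, 2, 3, 4)
  expect_equal(welch_t(x, x)$statistic, 0)
  expect_equal(welch_t(x, x)$p_value, 1)
  # one-sided p is half the two-sided p in the favoured tail
  set.seed(92)
  a <- rnorm(10, 1)
  b <- rnorm(10, 0)
  if (mean(a) > mean(b)) {
    expect_equal(welch_t(a, b, "greater")$p_value,
                 welch_t(a, b)$p_value / 2, tolerance = 1e-12)
  }
  # equal variances, equal n: df approaches the pooled value
  expect_equal(welch_t(c(1, 2, 3, 4), c(2, 3, 4, 5))$df, 6,
               tolerance = 1e-10)
  expect_error(welch_t(c(1, 1, 1), c(2, 2, 2)), "zero variance")
  expect_error(welch_t(1, c(1, 2)), "n >= 2")
})

test_that("partial correlation removes controls and nests Pearson", {
  # y = x exactly: perfect partial correlation regardless of control
  x <- 1:20
  z <- rnorm(20)
  res <- partial_correlation(x, x + 0, z)
  expect_equal(res$estimate, 1, tolerance = 1e-12)
  expect_lt(res$p_value, 1e-100)
  # conditional independence by construction
  set.seed(93)
  n <- 10000
  zz <- rnorm(n)
  xx <- zz + rnorm(n)
  yy <- zz + rnorm(n)
  pc <- partial_correlation(xx, yy, zz)
  expect_lt(abs(pc$estimate), 3 / sqrt(n))
  # raw correlation is strong, so the control is doing real work
  expect_gt(abs(partial_correlation(xx, yy)$estimate), 0.3)
  # k = 0 reduces exactly to the Pearson correlation t-test
  a <- rnorm(30)
  b <- a * 0.5 + rnorm(30)
  ours <- partial_correlation(a, b)
  ref <- stats::cor.test(a, b)
  expect_equal(ours$estimate, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
  expect_error(partial_correlation(a, b, cbind(a1 = 1:30, a2 = 2 * (1:30))),
               "collinear")
})

test_that("Fisher exact matches enumeration and the reference for small margins", {
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2))$p_value, 1)
  tab <- matrix(c(3, 0, 0, 3), 2)
  expect_equal(fisher_exact_2x2(tab)$p_value, 0.1, tolerance = 1e-12)
  set.seed(94)
  for (i in 1:30) {
    t2 <- matrix(sample(1:12, 4, replace = TRUE), 2)
    ours <- fisher_exact_2x2(t2)
    expect_equal(ours$p_value, oracle_fisher_two_sided(t2),
                 tolerance = 1e-12)
    expect_equal(ours$p_value, stats::fisher.test(t2)$p.value,
                 tolerance = 1e-9)
    # transpose invariance
    expect_equal(fisher_exact_2x2(t(t2))$p_value, ours$p_value,
                 tolerance = 1e-12)
    # one-sided tails against the reference
    expect_equal(fisher_exact_2x2(t2, "greater")$p_value,
                 stats::fisher.test(t2, alternative = "greater")$p.value,
                 tolerance = 1e-9)
    expect_equal(fisher_exact_2x2(t2, "less")$p_value,
                 stats::fisher.test(t2, alternative = "less")$p.value,
                 tolerance = 1e-9)
  }
  expect_error(fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2)), "margin")
})

test_that("regression F agrees with lm and with the t^2 identity", {
  set.seed(95)
  x <- rnorm(25)
  y <- 2 * x + rnorm(25, sd = 0.3)
  ours <- linear_regression_f(x, y)
  ref <- stats::summary.lm(stats::lm(y ~ x))
  expect_equal(ours$estimate, ref$coefficients["x", "Estimate"],
               tolerance = 1e-12)
  expect_equal(ours$statistic, unname(ref$fstatistic["value"]),
               tolerance = 1e-8)
  expect_equal(ours$statistic, ref$coefficients["x", "t value"]^2,
               tolerance = 1e-10)
  expect_equal(ours$p_value,
               stats::pf(ref$fstatistic["value"], 1, 23, lower.tail = FALSE),
               tolerance = 1e-12, ignore_attr = TRUE)
  # near-zero noise recovers the slope
  y2 <- 2 * x + rnorm(25, sd = 1e-8)
  expect_equal(linear_regression_f(x, y2)$estimate, 2, tolerance = 1e-6)
  # perfectly linear response: flagged exact fit, floor p
  exact <- linear_regression_f(x, 3 * x + 1)
  expect_equal(exact$note, "exact fit")
  expect_lt(exact$p_value, 1e-300)
  expect_error(linear_regression_f(rep(1, 10), rnorm(10)), "constant")
})

test_that("balanced two-way ANOVA matches projections and aov to 1e-8", {
  set.seed(96)
  a <- gl(2, 10)
  b <- rep(gl(2, 5), 2)
  y <- rnorm(20) + as.numeric(a) * 0.5 + as.numeric(b) * 0.2
  ours <- anova_two_way(y, a, b, interaction = TRUE)
  oracle <- oracle_anova_projection(y, a, b, interaction = TRUE)
  expect_equal(ours$ss[1:3], unname(oracle$ss), tolerance = 1e-8)
  expect_equal(ours$statistic[1:3], unname(oracle$f), tolerance = 1e-8)
  ref <- stats::anova(stats::aov(y ~ a * b))
  expect_equal(ours$statistic[1:3], ref[["F value"]][1:3], tolerance = 1e-8)
  expect_equal(ours$p_value[1:3], ref[["Pr(>F)"]][1:3], tolerance = 1e-8)
  # constant response: all F = 0, p = 1
  flat <- anova_two_way(rep(2.5, 20), a, b)
  expect_equal(flat$statistic[1:3], rep(0, 3))
  expect_equal(flat$p_value[1:3], rep(1, 3))
  # purely additive effects without noise: zero interaction SS
  y_add <- 2 + ifelse(a == "2", 1.5, 0) + ifelse(b == "2", -0.7, 0)
  add <- anova_two_way(y_add, a, b)
  expect_equal(add$ss[3], 0, tolerance = 1e-10)
  # unbalanced designs are refused with direction
  expect_error(anova_two_way(y[-1], a[-1], b[-1]), "unbalanced")
})
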