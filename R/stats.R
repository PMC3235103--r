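#' Welch two-sample t-test
#'
#' Unequal-variance t statistic
#' `t = (mean(x) - mean(y)) / sqrt(sx^2/nx + sy^2/ny)` with
#' Welch-Satterthwaite (generally fractional) degrees of freedom,
#' implemented directly from the formulas so results can be cross-checked
#' against independent evaluations.  With zero variance in both samples
#' and equal means the convention `t = 0, p = 1` is used; zero variance
#' with unequal means is an error.
#'
#' @param x,y Numeric samples, each of length >= 2.
#' @param tail `"two"`, `"greater"` (mean of `x` greater), or `"less"`.
#' @return List of class `flux_test`: `statistic`, `df`, `p_value`,
#'   `tail`, `estimate` (mean difference), `method`.
#' @export
welch_t <- function(x, y, tail = c("two", "greater", "less")) {
  tail <- match.arg(tail)
  if (length(x) < 2L || length(y) < 2L) stop("each sample needs n >= 2")
  nx <- length(x)
  ny <- length(y)
  vx <- stats::var(x)
  vy <- stats::var(y)
  d <- mean(x) - mean(y)
  se2 <- vx / nx + vy / ny
  if (se2 == 0) {
    if (d == 0) {
      return(.flux_test(0, Inf, 1, tail, 0, "Welch two-sample t"))
    }
    stop("zero variance with unequal means")
  }
  tstat <- d / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  if (df <= 1 + 1e-12) {
    message("Welch t with df <= 1: very low power")
  }
  .flux_test(tstat, df, .t_pvalue(tstat, df, tail), tail, d,
             "Welch two-sample t")
}

.t_pvalue <- function(tstat, df, tail) {
  switch(tail,
    two = 2 * pt(-abs(tstat), df),
    greater = pt(tstat, df, lower.tail = FALSE),
    less = pt(tstat, df)
  )
}

.flux_test <- function(statistic, df, p, tail, estimate, method,
                       note = NULL) {
  structure(
    list(statistic = statistic, df = df,
         p_value = min(max(p, 0), 1), tail = tail,
         estimate = estimate, method = method, note = note),
    class = "flux_test"
  )
}

#' @export
print.flux_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, df = %.4g, p = %.4g (%s-sided)\n",
              x$method, x$statistic, x$df, x$p_value, x$tail))
  if (!is.null(x$estimate)) cat(sprintf("  estimate = %.6g\n", x$estimate))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Partial correlation test
#'
#' Correlation between `x` and `y` after removing the least-squares effect
#' of the controlling covariates `z`: the residuals of `x ~ z` and `y ~ z`
#' (with intercept) are correlated, and
#' `t = r sqrt(n - 2 - k) / sqrt(1 - r^2)` on `n - 2 - k` degrees of
#' freedom, `k` the number of controls.  With no controls this is exactly
#' the Pearson correlation t-test.
#'
#' @param x,y Numeric vectors, same length `n >= k + 3`.
#' @param z Optional numeric vector, matrix, or data frame of controls.
#' @param tail As in [welch_t()].
#' @return A `flux_test`; `estimate` is the partial correlation.
#' @export
partial_correlation <- function(x, y, z = NULL,
                                tail = c("two", "greater", "less")) {
  tail <- match.arg(tail)
  n <- length(x)
  if (length(y) != n) stop("x and y lengths differ")
  zmat <- if (is.null(z)) {
    matrix(numeric(0), n, 0)
  } else {
    as.matrix(as.data.frame(z))
  }
  k <- ncol(zmat)
  if (n < k + 3L) stop("need n >= k + 3 observations")
  design <- cbind(1, zmat)
  qr_d <- qr(design)
  if (qr_d$rank < ncol(design)) stop("collinear controls")
  rx <- stats::resid(stats::lm.fit(design, x))
  ry <- stats::resid(stats::lm.fit(design, y))
  r <- sum(rx * ry) / sqrt(sum(rx^2) * sum(ry^2))
  df <- n - 2 - k
  if (abs(r) >= 1 - 1e-15) {
    p <- .Machine$double.xmin
    if (tail == "greater" && r < 0) p <- 1
    if (tail == "less" && r > 0) p <- 1
    return(.flux_test(sign(r) * Inf, df, p, tail, r,
                      "partial correlation t", note = "perfect correlation"))
  }
  tstat <- r * sqrt(df) / sqrt(1 - r^2)
  .flux_test(tstat, df, .t_pvalue(tstat, df, tail), tail, r,
             "partial correlation t")
}

#' Fisher's exact test for a 2x2 table
#'
#' Exact hypergeometric enumeration with fixed margins.  Each feasible
#' table's probability is computed from binomial coefficients (on the log
#' scale); the two-sided p-value sums the probabilities of all tables no
#' more probable than the observed one (the probability-ordering rule),
#' and one-sided p-values sum the appropriate tail of the top-left cell.
#'
#' @param table 2x2 matrix of non-negative integer counts; all four
#'   margins must be positive.
#' @param tail `"two"`, `"greater"` (observed top-left cell large, i.e.
#'   odds ratio > 1), or `"less"`.
#' @return A `flux_test`; `estimate` is the sample odds ratio, `statistic`
#'   the observed top-left count, `df` is `NA`.
#' @export
fisher_exact_2x2 <- function(table, tail = c("two", "greater", "less")) {
  tail <- match.arg(tail)
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2L, 2L))) stop("table must be 2x2")
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("counts must be non-negative integers")
  }
  r1 <- sum(tab[1L, ])
  r2 <- sum(tab[2L, ])
  c1 <- sum(tab[, 1L])
  c2 <- sum(tab[, 2L])
  if (min(r1, r2, c1, c2) == 0) stop("zero margin")
  n <- r1 + r2
  x_obs <- tab[1L, 1L]
  support <- max(0, c1 - r2):min(r1, c1)
  logp <- lchoose(r1, support) + lchoose(r2, c1 - support) - lchoose(n, c1)
  probs <- exp(logp - max(logp))
  probs <- probs / sum(probs)
  p_obs <- probs[support == x_obs]
  p <- switch(tail,
    two = sum(probs[probs <= p_obs * (1 + 1e-7)]),
    greater = sum(probs[support >= x_obs]),
    less = sum(probs[support <= x_obs])
  )
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  .flux_test(x_obs, NA_real_, p, tail, or, "Fisher exact 2x2")
}

#' Simple linear regression with F-test on the slope
#'
#' Ordinary least squares of `y` on `x`;
#' `F = MS_model / MS_residual` on (1, n - 2) degrees of freedom.  A
#' numerically exact fit (residual SS below machine-level tolerance
#' relative to the total SS) reports `p` at the machine floor with an
#' `"exact fit"` note rather than dividing by zero.
#'
#' @param x Predictor (not constant), length n >= 3.
#' @param y Response, same length.
#' @return A `flux_test`; `estimate` is the slope, `statistic` the F
#'   value, `df` is `c(1, n - 2)`.
#' @export
linear_regression_f <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y lengths differ")
  if (n < 3L) stop("need n >= 3")
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) stop("constant predictor")
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  fitted <- intercept + slope * x
  ss_tot <- sum((y - mean(y))^2)
  ss_res <- sum((y - fitted)^2)
  ss_mod <- ss_tot - ss_res
  df_res <- n - 2L
  if (ss_res <= 1e-14 * max(ss_tot, 1e-300)) {
    return(.flux_test(Inf, c(1, df_res), .Machine$double.xmin, "two",
                      slope, "regression F", note = "exact fit"))
  }
  f <- ss_mod / (ss_res / df_res)
  .flux_test(f, c(1, df_res), pf(f, 1, df_res, lower.tail = FALSE), "two",
             slope, "regression F")
}

#' Balanced two-way ANOVA
#'
#' Sequential sums of squares on a balanced layout (every factor-level
#' combination observed the same number of times; anything else is an
#' error directing the user to a regression formulation).  On a balanced
#' design the factor effects are orthogonal, so the main-effect and
#' interaction sums of squares come directly from the cell, row and
#' column means, and each term's F statistic is tested against the
#' residual mean square.
#'
#' @param response Numeric response.
#' @param factor_a,factor_b Factors (or coercible), >= 2 levels each.
#' @param interaction Include the A:B interaction term (requires within-
#'   cell replication)?
#' @return Tibble with columns `term`, `df`, `ss`, `ms`, `statistic`,
#'   `p_value`.
#' @export
anova_two_way <- function(response, factor_a, factor_b,
                          interaction = TRUE) {
  a <- as.factor(factor_a)
  b <- as.factor(factor_b)
  y <- as.numeric(response)
  if (length(a) != length(y) || length(b) != length(y)) {
    stop("lengths differ")
  }
  if (nlevels(a) < 2L || nlevels(b) < 2L) stop("need >= 2 levels per factor")
  counts <- table(a, b)
  if (length(unique(as.vector(counts))) != 1L || any(counts == 0)) {
    stop("unbalanced design: use a regression formulation instead")
  }
  n_cell <- counts[1L, 1L]
  if (interaction && n_cell < 2L) {
    stop("interaction requires within-cell replication")
  }
  grand <- mean(y)
  mean_a <- tapply(y, a, mean)
  mean_b <- tapply(y, b, mean)
  mean_ab <- tapply(y, list(a, b), mean)
  n_a <- as.vector(table(a))
  n_b <- as.vector(table(b))
  ss_a <- sum(n_a * (mean_a - grand)^2)
  ss_b <- sum(n_b * (mean_b - grand)^2)
  ss_ab <- n_cell * sum((mean_ab -
                           outer(mean_a, mean_b, "+") + grand)^2)
  ss_tot <- sum((y - grand)^2)
  cell_of <- mean_ab[cbind(as.integer(a), as.integer(b))]
  if (interaction) {
    ss_res <- sum((y - cell_of)^2)
    terms <- c("A", "B", "A:B")
    ss <- c(ss_a, ss_b, ss_ab)
    df <- c(nlevels(a) - 1L, nlevels(b) - 1L,
            (nlevels(a) - 1L) * (nlevels(b) - 1L))
  } else {
    ss_res <- ss_tot - ss_a - ss_b
    terms <- c("A", "B")
    ss <- c(ss_a, ss_b)
    df <- c(nlevels(a) - 1L, nlevels(b) - 1L)
  }
  df_res <- length(y) - 1L - sum(df)
  ms_res <- ss_res / df_res
  ms <- ss / df
  f <- if (ms_res > 0) ms / ms_res else ifelse(ss == 0, 0, Inf)
  p <- ifelse(is.infinite(f), .Machine$double.xmin,
              pf(f, df, df_res, lower.tail = FALSE))
  p[f == 0] <- 1
  tibble::tibble(
    term = c(terms, "Residuals"),
    df = c(df, df_res),
    ss = c(ss, ss_res),
    ms = c(ms, ms_res),
    statistic = c(f, NA_real_),
    p_value = c(p, NA_real_)
  )
}
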