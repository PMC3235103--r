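# Independent numerical oracles used across the suite.  These deliberately
# avoid the package's own code paths: quadrature for the spheroid
# descriptors, brute-force enumeration for clustering and exact tests,
# projection matrices for ANOVA.

# Volume of the ellipsoid of revolution with full axes L (major) and W:
# solid of revolution V = pi * int y(x)^2 dx, y(x) = (W/2) sqrt(1-(2x/L)^2).
oracle_volume <- function(L, W) {
  a <- L / 2
  b <- W / 2
  f <- function(x) b^2 * (1 - (x / a)^2)
  pi * stats::integrate(f, -a, a, rel.tol = 1e-12)$value
}

# Surface of revolution SA = 2 pi * int y sqrt(1 + y'^2) dx.  The integrand
# is rewritten as sqrt(y^2 + (y y')^2) so the tip singularity in y' cancels.
oracle_surface_area <- function(L, W) {
  a <- L / 2
  b <- W / 2
  f <- function(x) {
    y2 <- b^2 * (1 - (x / a)^2)
    yyp <- -b^2 * x / a^2
    sqrt(y2 + yyp^2)
  }
  2 * pi * stats::integrate(f, -a, a, rel.tol = 1e-10)$value
}

# Brute-force optimal 2-partition of 1-D points by within-cluster SS,
# searching every assignment (not only threshold splits).
oracle_kmeans2 <- function(x) {
  n <- length(x)
  best_wss <- Inf
  best <- NULL
  for (code in 1:(2^n - 2)) {
    grp <- as.logical(bitwAnd(code, 2^(seq_len(n) - 1L)))
    wss <- sum((x[grp] - mean(x[grp]))^2) +
      sum((x[!grp] - mean(x[!grp]))^2)
    if (wss < best_wss - 1e-12) {
      best_wss <- wss
      best <- grp
    }
  }
  list(wss = best_wss, groups = best)
}

# Exact two-sided Fisher p by direct enumeration using dhyper.
oracle_fisher_two_sided <- function(tab) {
  r1 <- sum(tab[1, ])
  r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(support, r1, r2, c1)
  p_obs <- stats::dhyper(tab[1, 1], r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Sequential balanced two-way ANOVA through explicit projection matrices.
oracle_anova_projection <- function(y, a, b, interaction = TRUE) {
  a <- as.factor(a)
  b <- as.factor(b)
  proj <- function(X) X %*% solve(crossprod(X), t(X))
  n <- length(y)
  X1 <- matrix(1, n, 1)
  Xa <- stats::model.matrix(~a)
  Xb <- stats::model.matrix(~b)
  Xab_main <- stats::model.matrix(~ a + b)
  Xfull <- if (interaction) stats::model.matrix(~ a * b) else Xab_main
  P1 <- proj(X1)
  Pa <- proj(Xa)
  Pab <- proj(Xab_main)
  Pf <- proj(Xfull)
  ss <- c(
    A = drop(t(y) %*% (Pa - P1) %*% y),
    B = drop(t(y) %*% (Pab - Pa) %*% y)
  )
  if (interaction) {
    ss <- c(ss, `A:B` = drop(t(y) %*% (Pf - Pab) %*% y))
  }
  ss_res <- drop(t(y) %*% (diag(n) - Pf) %*% y)
  df <- c(nlevels(a) - 1L, nlevels(b) - 1L)
  if (interaction) df <- c(df, (nlevels(a) - 1L) * (nlevels(b) - 1L))
  df_res <- n - 1L - sum(df)
  f <- (ss / df) / (ss_res / df_res)
  list(ss = ss, ss_res = ss_res, f = f, df = df, df_res = df_res)
}

# Analytic exhaustion time of a shared glucose pool under a pure
# exponential race (no lag, frequency-independent rates).
oracle_exhaustion_time <- function(counts, rates, yields, resource,
                                   upper = 100) {
  consumed <- function(t) {
    sum(yields * counts * (exp(rates * t) - 1)) - resource
  }
  stats::uniroot(consumed, c(0, upper), tol = 1e-13)$root
}
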