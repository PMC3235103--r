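#' Predicted non-fluorescent fraction under Malthusian selection
#'
#' Two-type selection model used for competitions against a fluorescent
#' common competitor: the non-fluorescent fraction after `T` generations is
#' `p0 e^{mT} / (p0 e^{mT} + 1 - p0)`, where `p0` is the initial
#' non-fluorescent fraction and `m` the Malthusian parameter of the focal
#' strain minus that of the marked competitor.  Equivalently, the logit of
#' the fraction is affine in `T` with slope `m`.
#'
#' @param p0 Initial non-fluorescent fraction, in (0, 1).
#' @param m Malthusian parameter difference, per generation.
#' @param T_gen Generations elapsed (vectorised).
#' @return Predicted fraction(s) in (0, 1).
#' @examples
#' predicted_fraction(0.5, 0.1, 6.658)  # ~0.6606
#' @export
predicted_fraction <- function(p0, m, T_gen) {
  if (p0 <= 0 || p0 >= 1) stop("p0 must lie in (0, 1)")
  stats::plogis(.logit(p0) + m * T_gen)
}

.logit <- function(p) log(p / (1 - p))

#' Generations elapsed after whole days of serial transfer
#'
#' A D-fold daily dilution implies `log2(D)` doublings per day once the
#' culture re-saturates, so `day * log2(D)` generations have elapsed; with
#' the standard 1:101 regime, 14 days is 93.2 generations (93 rounded).
#'
#' @param day Whole days (vectorised, >= 0).
#' @param dilution Dilution factor D > 1 (default 101).
#' @return Generations (doublings).
#' @examples
#' generations_from_day(0:3)   # 0, 6.658, 13.316, 19.974
#' @export
generations_from_day <- function(day, dilution = 101) {
  if (dilution <= 1) stop("dilution must be > 1")
  if (any(day < 0)) stop("day must be >= 0")
  day * log2(dilution)
}

#' Fit the selection model to one competition assay
#'
#' Least squares on the fraction scale (matching an `nls` fit of the
#' selection model), minimising
#' `sum((observed fraction - predicted fraction)^2)` over `(p0, m)` by
#' Gauss-Newton with the analytic Jacobian.  Initialised from the exact
#' logit-linear regression of observed fractions on `T` (with counts
#' clipped away from 0 and 1), which already solves noiseless data
#' exactly.
#'
#' @param assay Data frame with columns `T_generations` (or `day`, from
#'   which generations are derived), `n_nonfluor`, `n_fluor`; at least two
#'   distinct `T` values, positive totals per row.
#' @param dilution Dilution factor used when only `day` is present.
#' @param max_iter Gauss-Newton iteration cap.
#' @param tol Convergence threshold on the parameter step.
#' @return List of class `competition_fit`: `p0_hat`, `m_hat`, `rss`,
#'   `n_obs`, `iterations`, `converged`.
#' @export
fit_competition <- function(assay, dilution = 101, max_iter = 200L,
                            tol = 1e-10) {
  a <- tibble::as_tibble(assay)
  if (!"T_generations" %in% names(a)) {
    if (!"day" %in% names(a)) stop("need a T_generations or day column")
    a$T_generations <- generations_from_day(a$day, dilution)
  }
  need <- c("T_generations", "n_nonfluor", "n_fluor")
  if (!all(need %in% names(a))) {
    stop("need columns: ", paste(need, collapse = ", "))
  }
  total <- a$n_nonfluor + a$n_fluor
  if (any(total <= 0)) stop("each observation needs a positive total count")
  if (length(unique(a$T_generations)) < 2L) {
    stop("need at least 2 distinct generation values")
  }
  obs <- a$n_nonfluor / total
  if (all(obs == 0) || all(obs == 1)) stop("saturated assay")
  T_gen <- a$T_generations

  # Exact logit-linear initialisation (clip away from the boundary).
  clipped <- pmin(pmax(obs, 1 / (total + 1)), total / (total + 1))
  z <- .logit(clipped)
  m0 <- sum((T_gen - mean(T_gen)) * (z - mean(z))) /
    sum((T_gen - mean(T_gen))^2)
  a0 <- mean(z) - m0 * mean(T_gen)
  theta <- c(p0 = stats::plogis(a0), m = m0)

  eps <- 1e-12
  for (iter in seq_len(max_iter)) {
    p0 <- theta[["p0"]]
    m <- theta[["m"]]
    E <- exp(m * T_gen)
    S <- p0 * E + 1 - p0
    pred <- p0 * E / S
    r <- obs - pred
    J <- cbind(p0 = E / S^2,
               m = p0 * (1 - p0) * T_gen * E / S^2)
    step <- tryCatch(solve(crossprod(J), crossprod(J, r)),
                     error = function(e) NULL)
    if (is.null(step)) stop("singular Jacobian in competition fit")
    theta_new <- theta + as.vector(step)
    theta_new[["p0"]] <- min(max(theta_new[["p0"]], eps), 1 - eps)
    if (max(abs(theta_new - theta)) < tol) {
      theta <- theta_new
      return(.competition_fit(theta, obs, T_gen, iter, TRUE))
    }
    theta <- theta_new
  }
  stop(sprintf(
    "competition fit did not converge in %d iterations (p0=%.4g, m=%.4g)",
    max_iter, theta[["p0"]], theta[["m"]]
  ))
}

.competition_fit <- function(theta, obs, T_gen, iter, converged) {
  pred <- predicted_fraction(theta[["p0"]], theta[["m"]], T_gen)
  structure(
    list(
      p0_hat = theta[["p0"]], m_hat = theta[["m"]],
      rss = sum((obs - pred)^2), n_obs = length(obs),
      iterations = iter, converged = converged
    ),
    class = "competition_fit"
  )
}

#' Fit many competition assays and summarise per colony
#'
#' Fits every replicate with [fit_competition()], joins replicate
#' metadata, and reports the per-colony mean +/- SE of the Malthusian
#' difference.  Replicates whose fit fails are kept as flagged rows with
#' `NA` estimates rather than dropped silently.
#'
#' @param assays Data frame of stacked assays with a `replicate_id` column
#'   plus the columns required by [fit_competition()].
#' @param metadata Data frame with columns `replicate_id`, `colony_id`,
#'   `ploidy` (extra columns carried through).
#' @param dilution Dilution factor for day-to-generation conversion.
#' @return List with tibbles `replicates` (`p0_hat`, `m_hat`, `rss`,
#'   `n_obs`, `flag`, metadata) and `colonies` (`m_mean`, `m_se`, `n_reps`).
#' @export
fitness_table <- function(assays, metadata, dilution = 101) {
  a <- tibble::as_tibble(assays)
  if (!"replicate_id" %in% names(a)) stop("assays need a replicate_id column")
  fits <- lapply(split(a, a$replicate_id), function(one) {
    out <- tryCatch(fit_competition(one, dilution = dilution),
                    error = function(e) conditionMessage(e))
    if (is.character(out)) {
      tibble::tibble(replicate_id = one$replicate_id[1L],
                     p0_hat = NA_real_, m_hat = NA_real_, rss = NA_real_,
                     n_obs = nrow(one), flag = out)
    } else {
      tibble::tibble(replicate_id = one$replicate_id[1L],
                     p0_hat = out$p0_hat, m_hat = out$m_hat, rss = out$rss,
                     n_obs = out$n_obs, flag = NA_character_)
    }
  })
  reps <- dplyr::inner_join(dplyr::bind_rows(fits),
                            tibble::as_tibble(metadata), by = "replicate_id")
  reps <- dplyr::arrange(reps, .data$replicate_id)
  ok <- !is.na(reps$m_hat)
  colonies <- dplyr::summarise(
    dplyr::group_by(reps[ok, ], .data$colony_id, .data$ploidy),
    m_mean = mean(.data$m_hat),
    m_se = .se(.data$m_hat),
    n_reps = dplyr::n(),
    .groups = "drop"
  )
  list(replicates = reps, colonies = dplyr::arrange(colonies, .data$colony_id))
}
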