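#' Maximal growth rate from an optical-density series
#'
#' Natural-log-transforms the OD readings, drops points at or below the
#' instrument baseline (growth below the detection floor carries no slope
#' information), fits a local quadratic regression (loess, tricube
#' weights) through log OD versus time, and reports the maximum first
#' derivative of the smooth evaluated on a dense grid.  This is the
#' "steepest log-OD slope" definition of maximal growth rate, per hour.
#'
#' @param times Hours, strictly increasing.
#' @param od Optical densities, same length, >= 0.
#' @param span Loess span (fraction of points per local window),
#'   default 0.3.
#' @param baseline Detection floor; readings `<= baseline` are excluded
#'   from the log fit (default 0.04).
#' @param grid_step Evaluation grid spacing, hours (default 0.05).
#' @return List of class `growth_fit`: `max_rate` (per hour), `t_at_max`
#'   (hours), `n_used`, `flags` (character vector of quality notes).
#' @examples
#' t <- seq(0, 10, 0.25)
#' fit <- max_growth_rate(t, 0.05 * exp(0.35 * t))
#' fit$max_rate  # ~0.35
#' @export
max_growth_rate <- function(times, od, span = 0.3, baseline = OD_BASELINE,
                            grid_step = 0.05) {
  .check_series(times, od)
  keep <- od > baseline
  flags <- character(0)
  if (any(!keep)) {
    flags <- c(flags, sprintf("%d reading(s) at/below baseline excluded",
                              sum(!keep)))
  }
  t_u <- times[keep]
  y <- od[keep]
  if (length(t_u) < 12L) {
    stop("need at least 12 readings above baseline for the log fit")
  }
  if (any(y <= 0)) stop("non-positive OD after baseline handling")
  fit <- loess(log(y) ~ t_u, span = span, degree = 2,
               family = "gaussian",
               control = loess.control(surface = "direct"))
  grid <- seq(min(t_u), max(t_u), by = grid_step)
  sm <- predict(fit, newdata = data.frame(t_u = grid))
  deriv <- diff(sm) / diff(grid)
  i <- which.max(deriv)
  structure(
    list(
      max_rate = unname(deriv[i]),
      t_at_max = (grid[i] + grid[i + 1L]) / 2,
      n_used = length(t_u),
      flags = flags
    ),
    class = "growth_fit"
  )
}

#' Biomass production over the daily cycle
#'
#' Optical density at 24 hours minus optical density at the start, using
#' the nearest reading within +/- 0.25 h of each target time (no
#' interpolation beyond that window).
#'
#' @inheritParams max_growth_rate
#' @return OD units gained by 24 h.
#' @export
biomass_production <- function(times, od) {
  .check_series(times, od)
  od_at <- function(target) {
    i <- which.min(abs(times - target))
    if (abs(times[i] - target) > 0.25 + 1e-9) {
      stop(sprintf("no reading within 0.25 h of t = %g h", target))
    }
    od[i]
  }
  od_at(24) - od_at(0)
}

.check_series <- function(times, od) {
  if (length(times) != length(od)) stop("times and od lengths differ")
  if (length(times) < 2L) stop("series too short")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(od < 0)) stop("negative OD")
  invisible(NULL)
}

#' Summarise a plate of growth curves
#'
#' Fits [max_growth_rate()] and [biomass_production()] to every well of a
#' wide plate table, joins the well map, and summarises replicate wells
#' per colony (mean +/- SE).  Wells missing from the map are dropped with
#' a warning.  Results do not depend on well column order.
#'
#' @param plate Data frame: first column `time_h`, remaining columns one
#'   OD series per well.
#' @param well_map Data frame with columns `well_id`, `colony_id`,
#'   `ploidy` (extra metadata columns are carried through `wells`).
#' @param span Loess span passed to [max_growth_rate()].
#' @return List with tibbles `wells` (per-well fits) and `colonies`
#'   (per-colony `rate_mean`, `rate_se`, `biomass_mean`, `biomass_se`,
#'   `n_wells`).
#' @export
plate_summary <- function(plate, well_map, span = 0.3) {
  if (NROW(plate) == 0L || ncol(plate) < 2L) stop("empty plate")
  if (names(plate)[1L] != "time_h") stop("first plate column must be time_h")
  wells <- sort(setdiff(names(plate), "time_h"))
  unmapped <- setdiff(wells, well_map$well_id)
  if (length(unmapped)) {
    warning("unmapped well(s) excluded: ", paste(unmapped, collapse = ", "))
    wells <- setdiff(wells, unmapped)
  }
  if (!length(wells)) stop("no mapped wells")
  fits <- lapply(wells, function(w) {
    fit <- max_growth_rate(plate$time_h, plate[[w]], span = span)
    tibble::tibble(
      well_id = w,
      max_rate = fit$max_rate,
      t_at_max = fit$t_at_max,
      biomass = biomass_production(plate$time_h, plate[[w]])
    )
  })
  per_well <- dplyr::inner_join(dplyr::bind_rows(fits),
                                tibble::as_tibble(well_map), by = "well_id")
  per_well <- dplyr::arrange(per_well, .data$well_id)
  colonies <- dplyr::summarise(
    dplyr::group_by(per_well, .data$colony_id, .data$ploidy),
    rate_mean = mean(.data$max_rate),
    rate_se = .se(.data$max_rate),
    biomass_mean = mean(.data$biomass),
    biomass_se = .se(.data$biomass),
    n_wells = dplyr::n(),
    .groups = "drop"
  )
  list(wells = per_well, colonies = dplyr::arrange(colonies, .data$colony_id))
}

.se <- function(x) if (length(x) > 1L) sd(x) / sqrt(length(x)) else 0
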