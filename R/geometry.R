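#' Prolate-spheroid cell volume
#'
#' Yeast cells are modelled as prolate spheroids with full major axis `L`
#' and full minor axis `W`: `V = pi * L * W^2 / 6`.
#'
#' @param L Major axis, um (> 0).  Vectorised.
#' @param W Minor axis, um (> 0), `W <= L`.
#' @return Volume in um^3.
#' @examples
#' cell_volume(5, 5)   # sphere: 125 pi / 6
#' @export
cell_volume <- function(L, W) {
  .check_axes(L, W)
  pi * L * W^2 / 6
}

#' Prolate-spheroid eccentricity
#'
#' `e = sqrt(1 - (W/L)^2)`: 0 for a sphere, approaching 1 for highly
#' elongated cells.  Used as the shape descriptor alongside SA/V.
#'
#' @inheritParams cell_volume
#' @return Eccentricity in `[0, 1)`.
#' @export
cell_eccentricity <- function(L, W) {
  .check_axes(L, W)
  sqrt(pmax(0, 1 - (W / L)^2))
}

#' Prolate-spheroid surface area
#'
#' With semi-axes `a = L/2`, `b = W/2` and eccentricity `e`:
#' `SA = 2 pi b^2 (1 + (a / (b e)) * asin(e))`.
#' The removable singularity at `e = 0` is handled analytically: for
#' `e < 1e-6` the series `asin(e)/e = 1 + e^2/6 + O(e^4)` is used, which
#' returns the sphere value `pi d^2` exactly in the limit.
#'
#' @inheritParams cell_volume
#' @return Surface area in um^2.
#' @examples
#' cell_surface_area(5, 5)   # sphere: 25 pi
#' @export
cell_surface_area <- function(L, W) {
  .check_axes(L, W)
  a <- L / 2
  b <- W / 2
  e <- cell_eccentricity(L, W)
  ratio <- ifelse(e < 1e-6, (1 + e^2 / 6), asin(e) / e)
  2 * pi * b^2 * (1 + (a / b) * ratio)
}

.check_axes <- function(L, W) {
  if (any(L <= 0) || any(W <= 0)) stop("axes must be positive")
  if (any(W > L * (1 + 1e-12))) stop("minor axis W exceeds major axis L")
  invisible(NULL)
}

#' Validate and swap-correct cell measurements
#'
#' Manual ellipse drawing can transpose the axes; rows with `W_um > L_um`
#' are swapped (with a warning) rather than rejected.
#'
#' @param measurements Data frame with columns `cell_id`, `colony_id`,
#'   `ploidy`, `L_um`, `W_um`.
#' @return The corrected tibble.
#' @export
normalize_measurements <- function(measurements) {
  need <- c("cell_id", "colony_id", "ploidy", "L_um", "W_um")
  missing <- setdiff(need, names(measurements))
  if (length(missing)) {
    stop("missing columns: ", paste(missing, collapse = ", "))
  }
  m <- tibble::as_tibble(measurements)
  if (any(m$L_um <= 0) || any(m$W_um <= 0)) stop("axes must be positive")
  swap <- m$W_um > m$L_um
  if (any(swap)) {
    warning(sum(swap), " measurement(s) had W > L; axes swapped")
    tmp <- m$L_um[swap]
    m$L_um[swap] <- m$W_um[swap]
    m$W_um[swap] <- tmp
  }
  m
}

#' Per-cell shape descriptors with colony and ploidy summaries
#'
#' Computes volume, surface area, eccentricity and the surface-area to
#' volume ratio for every cell, then mean +/- SE (classical `sd/sqrt(n)`)
#' per colony and per ploidy level.
#'
#' @inheritParams normalize_measurements
#' @return List with tibbles `cells` (per-cell descriptors), `by_colony`
#'   and `by_ploidy` (columns `<var>_mean`, `<var>_se`, `n` for each of
#'   `V`, `SA`, `e`, `sa_v`).
#' @export
shape_table <- function(measurements) {
  if (NROW(measurements) == 0L) stop("no measurements")
  m <- normalize_measurements(measurements)
  cells <- dplyr::mutate(
    m,
    V = cell_volume(.data$L_um, .data$W_um),
    SA = cell_surface_area(.data$L_um, .data$W_um),
    e = cell_eccentricity(.data$L_um, .data$W_um),
    sa_v = .data$SA / .data$V
  )
  summarize_by <- function(df, ...) {
    dplyr::summarise(
      dplyr::group_by(df, ...),
      dplyr::across(
        dplyr::all_of(c("V", "SA", "e", "sa_v")),
        list(
          mean = mean,
          se = ~ if (length(.x) > 1L) sd(.x) / sqrt(length(.x)) else 0
        )
      ),
      n = dplyr::n(),
      .groups = "drop"
    )
  }
  list(
    cells = cells,
    by_colony = summarize_by(cells, .data$colony_id, .data$ploidy),
    by_ploidy = summarize_by(cells, .data$ploidy)
  )
}
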