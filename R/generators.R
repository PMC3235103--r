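#' Generate a plate-reader optical-density curve
#'
#' Runs the deterministic growth model for a single strain over a 48 h
#' window read every 15 minutes (the usual honeycomb-plate regime), adds
#' i.i.d. Gaussian read noise, and floors readings at the instrument
#' baseline (OD 0.04).  The inoculum mimics a 1:101 transfer of saturated
#' culture into fresh medium.
#'
#' @param strain A [strain_params()].
#' @param protocol A [transfer_protocol()]; `culture_volume` sets the scale
#'   and the read window runs 0-48 h regardless of `period`.
#' @param noise_sd Read-noise standard deviation, OD units, >= 0.
#' @param seed Optional integer seed.
#' @return Tibble with columns `time_h`, `od`.
#' @export
generate_od_curve <- function(strain, protocol = transfer_protocol(),
                              noise_sd = 0.005, seed = NULL) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  od <- .deterministic_od(strain, protocol)
  if (noise_sd > 0) od$od <- od$od + rnorm(nrow(od), 0, noise_sd)
  od$od <- pmax(od$od, OD_BASELINE)
  od
}

.deterministic_od <- function(strain, protocol,
                              hours = 48, step = 0.25) {
  res0 <- initial_resource(protocol)
  n0 <- res0 / strain$yield_per_cell / protocol$dilution_factor
  proto48 <- protocol
  proto48$period <- hours
  state <- sim_state(setNames(n0, strain$strain_id), res0)
  cyc <- simulate_cycle(state, list(strain), proto48,
                        dt = step, record_dt = step)
  tibble::tibble(
    time_h = cyc$trajectory$time_h,
    od = pmax(cyc$trajectory$od, OD_BASELINE)
  )
}

#' Generate flow-cytometry fluorescence events
#'
#' DNA-content fluorescence for a haploid/diploid mixture.  Unarrested
#' cultures put haploids in Gaussian G1/G2 peaks at `c` and `2c` and
#' diploids at `2c` and `4c` (so a haploid's G2 peak coincides with a
#' diploid's G1 peak).  Hydroxyurea-arrested cultures concentrate each
#' ploidy at its G1 peak, except an `escape_fraction` of cells that evade
#' arrest and remain at their G2 position.  Peak coefficient of variation
#' is 8% by default.
#'
#' @param n_events Number of cells measured, >= 1.
#' @param diploid_fraction True diploid fraction in `[0, 1]`.
#' @param arrested Logical; hydroxyurea-arrested sample?
#' @param escape_fraction Fraction escaping arrest, in `[0, 1]`.
#' @param g1_haploid Haploid G1 peak position `c` (arbitrary units).
#' @param cv Peak coefficient of variation.
#' @param g2_share Share of unarrested cells in G2.
#' @param sample_id Label carried on the output.
#' @param seed Optional integer seed.
#' @return A `flow_sample`: list with `sample_id`, `events` (numeric
#'   vector), `arrested`.
#' @export
generate_flow_sample <- function(n_events, diploid_fraction,
                                 arrested = FALSE, escape_fraction = 0.10,
                                 g1_haploid = 100, cv = 0.08,
                                 g2_share = 0.30, sample_id = "sample",
                                 seed = NULL) {
  if (n_events < 1) stop("n_events must be >= 1")
  stopifnot(diploid_fraction >= 0, diploid_fraction <= 1,
            escape_fraction >= 0, escape_fraction <= 1)
  if (!is.null(seed)) set.seed(seed)
  ploidy <- 1L + rbinom(n_events, 1L, diploid_fraction)
  in_g2 <- if (arrested) {
    runif(n_events) < escape_fraction
  } else {
    runif(n_events) < g2_share
  }
  peak <- g1_haploid * ploidy * ifelse(in_g2, 2, 1)
  events <- rnorm(n_events, peak, cv * peak)
  events <- pmax(events, 1e-6)
  structure(
    list(sample_id = sample_id, events = events, arrested = arrested),
    class = "flow_sample"
  )
}

#' Generate single-cell axis measurements
#'
#' Draws major axes `L` from a log-normal distribution and sets minor axes
#' `W = L * sqrt(1 - e^2)` with independent multiplicative log-normal
#' noise, calibrated so the expected prolate-spheroid volume equals the
#' strain's `mean_volume` exactly.  With `cv = 0` and eccentricity 0 every
#' cell is an identical sphere.
#'
#' @param strain A [strain_params()] supplying `mean_volume`, `eccentricity`,
#'   `ploidy` and the colony label.
#' @param n_cells Number of cells, >= 1.
#' @param cv Coefficient of variation of the major axis (default 0.07).
#' @param seed Optional integer seed.
#' @return Tibble with columns `cell_id`, `colony_id`, `ploidy`, `L_um`,
#'   `W_um` (the cell-measurement TSV schema).
#' @export
generate_cell_measurements <- function(strain, n_cells, cv = 0.07,
                                       seed = NULL) {
  if (n_cells < 1) stop("n_cells must be >= 1")
  if (cv < 0) stop("cv must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  e2 <- strain$eccentricity^2
  sdlog <- sqrt(log1p(cv^2))
  sdlog_w <- cv / 2
  # E[L^3] = exp(3 mu + 4.5 sdlog^2); W-noise exp(eps), eps ~ N(-sdlog_w^2,
  # sdlog_w^2) so E[exp(2 eps)] = 1 and E[V] = pi/6 (1-e^2) E[L^3].
  mu <- (log(6 * strain$mean_volume / (pi * (1 - e2))) - 4.5 * sdlog^2) / 3
  L <- exp(rnorm(n_cells, mu, sdlog))
  eps <- rnorm(n_cells, -sdlog_w^2, sdlog_w)
  W <- L * sqrt(1 - e2) * exp(eps)
  W <- pmin(W, L)   # manual ellipse convention: L is the major axis
  tibble::tibble(
    cell_id = sprintf("%s_c%04d", strain$strain_id, seq_len(n_cells)),
    colony_id = strain$strain_id,
    ploidy = strain$ploidy,
    L_um = L,
    W_um = W
  )
}

#' Generate competition count data against a marked competitor
#'
#' The true non-fluorescent fraction follows the two-type Malthusian model
#' (see [predicted_fraction()]) at `T = day * log2(D)` generations; observed
#' counts are binomial draws of `n_events` cells per day.
#'
#' @param p0 Initial non-fluorescent fraction, in (0, 1).
#' @param m Malthusian parameter difference, per generation.
#' @param days Integer days measured (default 0:3).
#' @param dilution Dilution factor D (default 101).
#' @param n_events Cells measured per day (default 10000).
#' @param replicate_id Label carried on the output.
#' @param seed Optional integer seed.
#' @return Tibble with columns `replicate_id`, `day`, `T_generations`,
#'   `n_nonfluor`, `n_fluor`.
#' @export
generate_competition_counts <- function(p0, m, days = 0:3, dilution = 101,
                                        n_events = 10000,
                                        replicate_id = "rep1",
                                        seed = NULL) {
  if (p0 <= 0 || p0 >= 1) stop("p0 must lie in (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  T_gen <- generations_from_day(days, dilution)
  frac <- predicted_fraction(p0, m, T_gen)
  n_nf <- rbinom(length(days), n_events, frac)
  tibble::tibble(
    replicate_id = replicate_id,
    day = days,
    T_generations = T_gen,
    n_nonfluor = n_nf,
    n_fluor = n_events - n_nf
  )
}

#' Glucose depletion curve for a mixed culture
#'
#' Glucose (% w/v) remaining in the medium over one growth cycle:
#' the fresh-medium 2% w/v minus the cumulative yield-weighted cell
#' production of the growth model.  Non-increasing in time; constant while
#' every strain is still in lag.
#'
#' @param strains List of [strain_params()].
#' @param counts Named initial counts.
#' @param times Hours at which to report, within `[0, 24]`.
#' @param protocol A [transfer_protocol()].
#' @param dt Integration sub-step, hours.
#' @return Tibble with columns `time_h`, `glucose_pct`.
#' @export
generate_glucose_series <- function(strains, counts,
                                    times = c(0, 2, 4, 6, 8, 24),
                                    protocol = transfer_protocol(),
                                    dt = 0.25) {
  if (any(times < 0) || any(times > 24)) stop("times must lie in [0, 24]")
  state <- sim_state(counts, initial_resource(protocol))
  proto <- protocol
  proto$period <- 24
  cyc <- simulate_cycle(state, strains, proto, dt = dt, record_dt = dt)
  traj <- cyc$trajectory[!duplicated(cyc$trajectory$time_h), ]
  res0 <- initial_resource(protocol)
  glu <- approx(traj$time_h, traj$resource, xout = times, rule = 2)$y
  tibble::tibble(
    time_h = times,
    glucose_pct = GLUCOSE_PCT_WV * glu / res0
  )
}
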