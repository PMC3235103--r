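#' Strain parameters for the batch-culture simulator
#'
#' Bundles the life-history parameters of one strain: the lag before growth
#' resumes after transfer into fresh medium, the maximal exponential growth
#' rate during the fermentative (log) phase, the glucose consumed per new
#' cell, an optional frequency-dependence coefficient, and the cell-geometry
#' parameters used by the imaging and flow-cytometry generators.
#'
#' The per-hour Malthusian growth rate realised in mixed culture is
#' `growth_rate + fds_slope * (1 - f)`, where `f` is the strain's current
#' frequency.  A positive `fds_slope` is therefore an advantage when rare
#' that declines linearly with the strain's own frequency (negative
#' frequency-dependent selection); in monoculture (`f = 1`) the term
#' vanishes, so plate-based growth assays see `growth_rate` alone.
#'
#' @param strain_id Character label.
#' @param ploidy Integer, 1 (haploid) or 2 (diploid).
#' @param lag Hours of post-transfer quiescence, >= 0.
#' @param growth_rate Maximal exponential growth rate, per hour, > 0.
#' @param yield_per_cell Grams of glucose consumed per new cell, > 0.
#' @param fds_slope Frequency-dependence coefficient (per hour on the
#'   Malthusian scale, per unit own-frequency).  0 disables it.
#' @param mean_volume Mean single-cell volume, um^3.
#' @param eccentricity Target cell eccentricity in `[0, 1)`.
#'
#' @return A `strain_params` list.
#' @examples
#' strain_params("anc", ploidy = 1)
#' @export
strain_params <- function(strain_id,
                          ploidy = 1L,
                          lag = 1.5,
                          growth_rate = 0.46,
                          yield_per_cell = 1e-10 * mean_volume / 65,
                          fds_slope = 0,
                          mean_volume = if (ploidy == 1L) 65 else 115,
                          eccentricity = if (ploidy == 1L) 0.50 else 0.57) {
  stopifnot(is.character(strain_id), length(strain_id) == 1L)
  ploidy <- as.integer(ploidy)
  if (!ploidy %in% c(1L, 2L)) stop("ploidy must be 1 or 2")
  if (lag < 0) stop("lag must be >= 0")
  if (growth_rate <= 0) stop("growth_rate must be > 0")
  if (yield_per_cell <= 0) stop("yield_per_cell must be > 0")
  if (eccentricity < 0 || eccentricity >= 1) {
    stop("eccentricity must lie in [0, 1)")
  }
  structure(
    list(
      strain_id = strain_id, ploidy = ploidy, lag = lag,
      growth_rate = growth_rate, yield_per_cell = yield_per_cell,
      fds_slope = fds_slope, mean_volume = mean_volume,
      eccentricity = eccentricity
    ),
    class = "strain_params"
  )
}

#' Serial-transfer protocol
#'
#' Describes the daily dilution regime: a `dilution_factor`-fold dilution
#' (1 part culture into `dilution_factor - 1` parts fresh medium is treated
#' as sampling each cell with probability `1 / dilution_factor`) into
#' `culture_volume` mL of fresh medium every `period` hours, for `n_days`
#' transfers.  A D-fold dilution implies `log2(D)` population doublings per
#' cycle once the culture re-saturates; the default 1:101 daily regime gives
#' 6.658 generations per day.
#'
#' @param dilution_factor Dilution factor D > 1 (default 101).
#' @param culture_volume Culture volume in mL (default 10).
#' @param period Hours between transfers (default 24).
#' @param n_days Number of transfer cycles, >= 1.
#' @return A `transfer_protocol` list; `generations_per_transfer` is
#'   precomputed as `log2(dilution_factor)`.
#' @export
transfer_protocol <- function(dilution_factor = 101,
                              culture_volume = 10,
                              period = 24,
                              n_days = 14L) {
  if (dilution_factor <= 1) stop("dilution_factor must be > 1")
  if (culture_volume <= 0) stop("culture_volume must be > 0")
  if (period <= 0) stop("period must be > 0")
  n_days <- as.integer(n_days)
  if (n_days < 1L) stop("n_days must be >= 1")
  structure(
    list(
      dilution_factor = dilution_factor,
      culture_volume = culture_volume,
      period = period,
      n_days = n_days,
      generations_per_transfer = log2(dilution_factor)
    ),
    class = "transfer_protocol"
  )
}

#' Initial glucose mass for a protocol
#'
#' Grams of glucose in a fresh culture: 2% w/v times the culture volume.
#' @param protocol A [transfer_protocol()].
#' @return Grams of glucose.
#' @export
initial_resource <- function(protocol) {
  GLUCOSE_G_PER_ML * protocol$culture_volume
}

#' Simulator state within one transfer cycle
#'
#' @param counts Named numeric vector of cell counts (>= 0) per strain.
#' @param resource Grams of glucose remaining, >= 0.
#' @param time_in_cycle Hours elapsed since the last transfer.
#' @return A `sim_state` list.
#' @export
sim_state <- function(counts, resource, time_in_cycle = 0) {
  if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
    stop("counts must be a named vector")
  }
  if (any(counts < 0)) stop("counts must be non-negative")
  if (resource < 0) stop("resource must be non-negative")
  structure(
    list(
      counts = counts, resource = resource,
      time_in_cycle = time_in_cycle
    ),
    class = "sim_state"
  )
}

#' Full simulator configuration
#'
#' @param seed Integer seed; a fixed seed makes every emitted table
#'   reproducible byte for byte.
#' @param strains List of [strain_params()].
#' @param protocol A [transfer_protocol()].
#' @param initial_counts Named numeric vector, one entry per strain.
#' @param od_noise_sd Gaussian read noise on simulated OD curves (OD units).
#' @param count_noise `"binomial"` for stochastic bottlenecks, `"none"` for
#'   deterministic rounding.
#' @param diploidization_rate Per-cell per-generation probability that a
#'   haploid cell spontaneously converts to a diploid (autodiploidization);
#'   must lie in `[0, 1e-2]`.  Converted cells join the first diploid strain
#'   in `strains`.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed,
                       strains,
                       protocol = transfer_protocol(),
                       initial_counts,
                       od_noise_sd = 0.005,
                       count_noise = c("binomial", "none"),
                       diploidization_rate = 0) {
  count_noise <- match.arg(count_noise)
  stopifnot(is.list(strains), length(strains) >= 1L)
  ids <- vapply(strains, function(s) s$strain_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate strain_id")
  if (!setequal(names(initial_counts), ids)) {
    stop("initial_counts names must match strain ids")
  }
  if (diploidization_rate < 0 || diploidization_rate > 1e-2) {
    stop("diploidization_rate must lie in [0, 1e-2]")
  }
  if (diploidization_rate > 0 &&
      !any(vapply(strains, function(s) s$ploidy, integer(1)) == 2L)) {
    stop("diploidization requires at least one diploid strain as target")
  }
  structure(
    list(
      seed = as.integer(seed), strains = strains, protocol = protocol,
      initial_counts = initial_counts[ids], od_noise_sd = od_noise_sd,
      count_noise = count_noise, diploidization_rate = diploidization_rate
    ),
    class = "sim_config"
  )
}
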