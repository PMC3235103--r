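#' Simulate one batch-culture growth cycle
#'
#' Deterministic within-cycle dynamics: each strain sits idle for its lag,
#' then grows exponentially at the effective per-hour Malthusian rate
#' `growth_rate + fds_slope * (1 - f)` (with `f` its current frequency)
#' until the shared glucose pool is exhausted, at which point all growth
#' stops.  Glucose decreases by `yield_per_cell` grams per new cell.  The
#' integrator freezes rates within each sub-step of length `dt` (growth is
#' then exactly exponential within the step) and solves the exhaustion time
#' inside the final step by root finding, so with frequency-independent
#' rates the trajectory is exact up to the per-step rate refresh.
#'
#' @param state A [sim_state()]; `resource` must be positive and at least
#'   one strain count positive.
#' @param strains List of [strain_params()] covering every name in
#'   `state$counts`.
#' @param protocol A [transfer_protocol()]; the cycle runs for
#'   `protocol$period` hours.
#' @param dt Integration sub-step, hours (default 0.25; must divide evenly
#'   into the recording grid).
#' @param record_dt Spacing of recorded trajectory rows, hours (default 1).
#' @return List with `state` (the end-of-cycle [sim_state()]) and
#'   `trajectory`, a tibble with columns `time_h`, `strain`, `count`,
#'   `frequency`, `resource`, `od` (OD is proportional to total biovolume
#'   density; see package constants).
#' @export
simulate_cycle <- function(state, strains, protocol, dt = 0.25,
                           record_dt = 1) {
  strains <- .index_strains(strains, names(state$counts))
  if (sum(state$counts) <= 0) stop("extinct culture")
  if (state$resource <= 0) stop("resource must be positive at cycle start")
  if (record_dt < dt) dt <- record_dt
  n_sub <- round(record_dt / dt)
  if (abs(n_sub * dt - record_dt) > 1e-9) {
    stop("dt must divide record_dt")
  }
  par <- .strain_matrix(strains)
  counts <- state$counts
  resource <- state$resource
  t <- state$time_in_cycle
  times <- seq(t, protocol$period, by = record_dt)
  n_strain <- length(counts)
  rec_count <- matrix(NA_real_, length(times), n_strain,
                      dimnames = list(NULL, names(counts)))
  rec_res <- numeric(length(times))
  rec_count[1L, ] <- counts
  rec_res[1L] <- resource
  vols <- par[, "mean_volume"]

  for (i in seq_along(times)[-1L]) {
    for (s in seq_len(n_sub)) {
      step <- .advance(counts, resource, t, dt, par)
      counts <- step$counts
      resource <- step$resource
      t <- t + dt
    }
    rec_count[i, ] <- counts
    rec_res[i] <- resource
  }

  od <- OD_PER_BIOVOL * (rec_count %*% vols)[, 1L] / protocol$culture_volume
  traj <- tibble::tibble(
    time_h = rep(times, each = n_strain),
    strain = rep(names(counts), length(times)),
    count = as.vector(t(rec_count)),
    frequency = as.vector(t(rec_count / rowSums(rec_count))),
    resource = rep(rec_res, each = n_strain),
    od = rep(od, each = n_strain)
  )
  list(
    state = sim_state(counts, resource, time_in_cycle = t),
    trajectory = traj
  )
}

# One frozen-rate sub-step: exponential growth for strains past lag while
# glucose lasts; exhaustion time within the step solved by uniroot.
.advance <- function(counts, resource, t, dt, par) {
  if (resource <= 0) return(list(counts = counts, resource = resource))
  total <- sum(counts)
  if (total <= 0) stop("extinct culture")
  f <- counts / total
  active <- counts > 0 & t >= par[, "lag"] - 1e-12
  rate <- pmax(0, par[, "growth_rate"] + par[, "fds_slope"] * (1 - f))
  rate[!active] <- 0
  if (all(rate == 0)) return(list(counts = counts, resource = resource))
  y <- par[, "yield_per_cell"]
  grown <- counts * exp(rate * dt)
  used <- sum(y * (grown - counts))
  if (used <= resource) {
    return(list(counts = grown, resource = resource - used))
  }
  consume <- function(tau) sum(y * counts * (exp(rate * tau) - 1)) - resource
  tau <- uniroot(consume, c(0, dt), tol = 1e-12)$root
  list(counts = counts * exp(rate * tau), resource = 0)
}

.strain_matrix <- function(strains) {
  m <- t(vapply(
    strains,
    function(s) c(lag = s$lag, growth_rate = s$growth_rate,
                  yield_per_cell = s$yield_per_cell,
                  fds_slope = s$fds_slope, mean_volume = s$mean_volume),
    numeric(5)
  ))
  rownames(m) <- vapply(strains, function(s) s$strain_id, character(1))
  m
}

.index_strains <- function(strains, ids) {
  names(strains) <- vapply(strains, function(s) s$strain_id, character(1))
  missing <- setdiff(ids, names(strains))
  if (length(missing)) {
    stop("no strain_params for: ", paste(missing, collapse = ", "))
  }
  strains[ids]
}

#' Apply the daily dilution bottleneck
#'
#' Each strain's count is thinned with probability `1 / dilution_factor`
#' (independent binomial draws per strain; at the ~1e8-cell scale of these
#' cultures this is indistinguishable from joint hypergeometric sampling),
#' or divided and rounded deterministically when `count_noise = "none"`.
#' The glucose pool is reset to that of fresh medium.
#'
#' @param state A [sim_state()] with positive total count.
#' @param protocol A [transfer_protocol()].
#' @param count_noise `"binomial"` or `"none"`.
#' @return A fresh-cycle [sim_state()] (`time_in_cycle = 0`).
#' @export
bottleneck <- function(state, protocol, count_noise = c("binomial", "none")) {
  count_noise <- match.arg(count_noise)
  if (sum(state$counts) <= 0) stop("extinct culture")
  p <- 1 / protocol$dilution_factor
  counts <- state$counts
  new <- if (count_noise == "none") {
    round(counts / protocol$dilution_factor)
  } else {
    vapply(counts, .rbinom_large, numeric(1), prob = p)
  }
  names(new) <- names(counts)
  sim_state(new, initial_resource(protocol), time_in_cycle = 0)
}

# rbinom() needs an integer-ranged size; fall back to the normal
# approximation for astronomically large counts (never reached at defaults).
.rbinom_large <- function(n, prob) {
  n <- round(n)
  if (n == 0) return(0)
  if (n < 2^31 - 1) return(rbinom(1L, n, prob))
  mu <- n * prob
  max(0, round(rnorm(1L, mu, sqrt(mu * (1 - prob)))))
}

#' Simulate a serial-transfer evolution experiment
#'
#' Composes [simulate_cycle()] and [bottleneck()] for `n_days` daily
#' transfers.  When `diploidization_rate > 0`, haploid cells convert to the
#' first diploid strain at the end of each cycle, with per-cell probability
#' `1 - (1 - rate)^g` where `g = log2(D)` generations elapse per cycle
#' (rare events, so end-of-cycle application is equivalent to
#' per-generation draws to first order).
#'
#' @param config A [sim_config()].
#' @param dt Integration sub-step passed to [simulate_cycle()].
#' @return Tidy tibble with columns `day`, `strain`, `count`, `frequency`,
#'   `diploid_fraction`; day 0 rows give the initial composition, later
#'   rows the end-of-cycle composition before that day's bottleneck.
#' @export
simulate_evolution <- function(config, dt = 0.25) {
  set.seed(config$seed)
  protocol <- config$protocol
  strains <- .index_strains(config$strains, names(config$initial_counts))
  ploidies <- vapply(strains, function(s) s$ploidy, integer(1))
  target_2n <- names(ploidies)[ploidies == 2L][1L]
  state <- sim_state(config$initial_counts, initial_resource(protocol))
  gens <- protocol$generations_per_transfer
  p_conv <- 1 - (1 - config$diploidization_rate)^gens

  rows <- vector("list", protocol$n_days + 1L)
  rows[[1L]] <- .evo_row(0L, state$counts, ploidies)
  for (day in seq_len(protocol$n_days)) {
    cyc <- simulate_cycle(state, strains, protocol, dt = dt,
                          record_dt = protocol$period)
    state <- cyc$state
    if (p_conv > 0) {
      counts <- state$counts
      for (h in names(ploidies)[ploidies == 1L]) {
        k <- .rbinom_large(counts[[h]], p_conv)
        counts[[h]] <- counts[[h]] - k
        counts[[target_2n]] <- counts[[target_2n]] + k
      }
      state <- sim_state(counts, state$resource, state$time_in_cycle)
    }
    rows[[day + 1L]] <- .evo_row(day, state$counts, ploidies)
    state <- bottleneck(state, protocol, config$count_noise)
    if (sum(state$counts) <= 0) stop("extinct culture")
  }
  dplyr::bind_rows(rows)
}

.evo_row <- function(day, counts, ploidies) {
  total <- sum(counts)
  tibble::tibble(
    day = day,
    strain = names(counts),
    count = unname(counts),
    frequency = unname(counts) / total,
    diploid_fraction = sum(counts[ploidies == 2L]) / total
  )
}
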