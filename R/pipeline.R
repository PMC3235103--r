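#' Build a named simulation scenario
#'
#' Three built-in study designs over the serial-transfer system:
#' \describe{
#'   \item{neutral}{Haploid and diploid strains with identical life-history
#'     parameters and no frequency dependence, mixed 50:50.  Every assay is
#'     expected to be null.}
#'   \item{diploid_fds}{Equal maximal growth rates, but both strains carry a
#'     rare-type advantage (`fds_slope = 0.04`/h on the Malthusian scale,
#'     declining with own frequency).  Diploids start at frequency 0.01,
#'     rise, and plateau near 0.5 where the effective rates equalise --
#'     while monoculture growth assays (frequency 1) see no rate
#'     difference.}
#'   \item{late_sweeper}{A single diploid lineage seeded at 5% carries a
#'     frequency-dependent competitive advantage (`fds_slope = 0.10`/h)
#'     invisible to monoculture growth assays; it sweeps to fixation.}
#' }
#'
#' @param scenario One of `"neutral"`, `"diploid_fds"`, `"late_sweeper"`.
#' @param seed Integer seed.
#' @param n_days Number of daily transfers (default 14).
#' @param count_noise Bottleneck noise mode (default `"binomial"`).
#' @return A [sim_config()].
#' @export
scenario_config <- function(scenario = c("neutral", "diploid_fds",
                                         "late_sweeper"),
                            seed, n_days = 14L,
                            count_noise = "binomial") {
  scenario <- match.arg(scenario)
  protocol <- transfer_protocol(n_days = n_days)
  sat <- initial_resource(protocol) / 1e-10     # reference haploid cells
  n0 <- sat / protocol$dilution_factor          # fresh-inoculum total
  cfg <- switch(scenario,
    neutral = sim_config(
      seed = seed,
      strains = list(
        strain_params("H", ploidy = 1L),
        strain_params("D", ploidy = 2L)
      ),
      protocol = protocol,
      initial_counts = c(H = 0.5 * n0, D = 0.5 * n0),
      count_noise = count_noise
    ),
    diploid_fds = sim_config(
      seed = seed,
      strains = list(
        strain_params("H", ploidy = 1L, fds_slope = 0.04),
        strain_params("D", ploidy = 2L, fds_slope = 0.04)
      ),
      protocol = protocol,
      initial_counts = c(H = 0.99 * n0, D = 0.01 * n0),
      count_noise = count_noise
    ),
    late_sweeper = sim_config(
      seed = seed,
      strains = list(
        strain_params("H", ploidy = 1L),
        strain_params("D_sweep", ploidy = 2L, fds_slope = 0.10)
      ),
      protocol = protocol,
      initial_counts = c(H = 0.95 * n0, D_sweep = 0.05 * n0),
      count_noise = count_noise
    )
  )
  cfg$scenario <- scenario
  cfg
}

#' Simulate a competition assay against the common competitor
#'
#' Closed-loop competition: the focal strain and an unmarked-equivalent of
#' the fluorescent reference strain are co-cultured through daily
#' transfers by the growth model itself (so frequency-dependent effects
#' act), and each day 10,000 cells are sampled binomially, mimicking the
#' flow-cytometry count data.
#'
#' @param strain Focal [strain_params()].
#' @param competitor Reference [strain_params()] (default: ancestral-like
#'   haploid with no frequency dependence).
#' @param days Days measured (default 0:3).
#' @param n_events Cells counted per day.
#' @param protocol A [transfer_protocol()].
#' @param replicate_id Label for the output.
#' @param seed Optional integer seed.
#' @param dt Integration sub-step.
#' @return Counts tibble as in [generate_competition_counts()].
#' @export
simulate_competition_assay <- function(strain,
                                       competitor =
                                         strain_params("competitor"),
                                       days = 0:3, n_events = 10000,
                                       protocol = transfer_protocol(),
                                       replicate_id = "rep1",
                                       seed = NULL, dt = 0.25) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(strain$strain_id != competitor$strain_id)
  sat <- initial_resource(protocol) / competitor$yield_per_cell
  n0 <- sat / protocol$dilution_factor
  counts <- setNames(c(0.5 * n0, 0.5 * n0),
                     c(strain$strain_id, competitor$strain_id))
  state <- sim_state(counts, initial_resource(protocol))
  strains <- list(strain, competitor)
  freq <- numeric(max(days) + 1L)
  freq[1L] <- 0.5
  for (day in seq_len(max(days))) {
    cyc <- simulate_cycle(state, strains, protocol, dt = dt,
                          record_dt = protocol$period)
    freq[day + 1L] <- cyc$state$counts[[strain$strain_id]] /
      sum(cyc$state$counts)
    state <- bottleneck(cyc$state, protocol, "binomial")
  }
  f_obs <- freq[days + 1L]
  n_nf <- rbinom(length(days), n_events, f_obs)
  tibble::tibble(
    replicate_id = replicate_id,
    day = days,
    T_generations = generations_from_day(days, protocol$dilution_factor),
    n_nonfluor = n_nf,
    n_fluor = n_events - n_nf
  )
}

#' Run one end-to-end scenario
#'
#' Composes the full analysis loop on simulated data: evolution of strain
#' frequencies under daily transfer; replicate plate-reader growth curves
#' summarised per strain; competition assays against the common
#' competitor with Malthusian fits; arrested flow samples at day 0 and the
#' final day analysed by the ploidy module; and an inferential report
#' (Welch t on growth rate, biomass and competitive fitness by ploidy;
#' Fisher exact on the day-0 versus final-day gated flow counts).
#' Identical configurations (including seed) reproduce identical tables.
#'
#' @param config A [sim_config()] from [scenario_config()] (or any config
#'   whose strains carry ploidy labels).
#' @param n_wells Replicate plate wells per strain (default 5).
#' @param n_comp_reps Replicate competition assays per strain (default 4).
#' @param flow_events Events per arrested flow sample (default 30000).
#' @return List of class `run_report`: `scenario`, `evolution`, `growth`,
#'   `competition`, `ploidy`, `stats`, `provenance`.
#' @export
run_scenario <- function(config, n_wells = 5L, n_comp_reps = 4L,
                         flow_events = 30000L) {
  strains <- config$strains
  ids <- vapply(strains, function(s) s$strain_id, character(1))
  ploidies <- vapply(strains, function(s) s$ploidy, integer(1))

  evolution <- simulate_evolution(config)

  # Plate growth assay: strains are assayed in monoculture, so any
  # frequency-dependent advantage is invisible here by construction.
  set.seed(config$seed + 1L)
  plate <- NULL
  map_rows <- list()
  for (i in seq_along(strains)) {
    for (w in seq_len(n_wells)) {
      curve <- generate_od_curve(strains[[i]], config$protocol,
                                 noise_sd = config$od_noise_sd)
      well <- sprintf("%s_w%d", ids[i], w)
      if (is.null(plate)) plate <- tibble::tibble(time_h = curve$time_h)
      plate[[well]] <- curve$od
      map_rows[[well]] <- tibble::tibble(
        well_id = well, colony_id = ids[i], ploidy = ploidies[i]
      )
    }
  }
  growth <- plate_summary(plate, dplyr::bind_rows(map_rows))

  # Competition against the common competitor (closed loop).
  set.seed(config$seed + 2L)
  assays <- list()
  meta <- list()
  for (i in seq_along(strains)) {
    for (r in seq_len(n_comp_reps)) {
      rid <- sprintf("%s_r%d", ids[i], r)
      assays[[rid]] <- simulate_competition_assay(
        strains[[i]], protocol = config$protocol, replicate_id = rid
      )
      meta[[rid]] <- tibble::tibble(
        replicate_id = rid, colony_id = ids[i], ploidy = ploidies[i]
      )
    }
  }
  competition <- fitness_table(dplyr::bind_rows(assays),
                               dplyr::bind_rows(meta),
                               dilution = config$protocol$dilution_factor)

  # Ploidy change, estimated the way the experiment estimates it: from
  # hydroxyurea-arrested flow samples, not from the simulator's truth.
  set.seed(config$seed + 3L)
  last_day <- config$protocol$n_days
  true0 <- evolution$diploid_fraction[evolution$day == 0][1L]
  true14 <- evolution$diploid_fraction[evolution$day == last_day][1L]
  esc <- 0.10
  flow0 <- generate_flow_sample(flow_events, true0, arrested = TRUE,
                                escape_fraction = esc, sample_id = "day0")
  flow14 <- generate_flow_sample(flow_events, true14, arrested = TRUE,
                                 escape_fraction = esc,
                                 sample_id = sprintf("day%d", last_day))
  est0 <- diploid_fraction(flow0, 100, esc)
  est14 <- diploid_fraction(flow14, 100, esc)
  ploidy_tab <- tibble::tibble(
    day = c(0L, last_day),
    true_fraction = c(true0, true14),
    estimated_fraction = c(est0, est14)
  )

  stats_tab <- .scenario_stats(growth, competition, flow0, flow14,
                               est0, est14)

  structure(
    list(
      scenario = config$scenario %||% "custom",
      evolution = evolution,
      growth = growth,
      competition = competition,
      ploidy = ploidy_tab,
      stats = stats_tab,
      provenance = list(
        config_hash = rlang::hash(config),
        seed = config$seed,
        package_version = as.character(utils::packageVersion("ploidyflux"))
      )
    ),
    class = "run_report"
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

.scenario_stats <- function(growth, competition, flow0, flow14,
                            est0, est14) {
  rows <- list()
  add <- function(name, res) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      test = name,
      statistic = res$statistic[1L],
      df = res$df[1L],
      p_value = res$p_value,
      estimate = res$estimate %||% NA_real_
    )
  }
  wells <- growth$wells
  by_ploidy <- function(v) split(v, wells$ploidy == 2L)
  if (length(unique(wells$ploidy)) == 2L) {
    g <- by_ploidy(wells$max_rate)
    add("growth_rate_diploid_vs_haploid",
        welch_t(g[["TRUE"]], g[["FALSE"]]))
    b <- by_ploidy(wells$biomass)
    add("biomass_diploid_vs_haploid", welch_t(b[["TRUE"]], b[["FALSE"]]))
  }
  reps <- competition$replicates
  reps <- reps[!is.na(reps$m_hat), ]
  if (length(unique(reps$ploidy)) == 2L) {
    m <- split(reps$m_hat, reps$ploidy == 2L)
    add("competitive_m_diploid_vs_haploid",
        welch_t(m[["TRUE"]], m[["FALSE"]]))
  }
  gate <- 150
  tab <- rbind(
    day0 = c(above = sum(flow0$events > gate),
             below = sum(flow0$events <= gate)),
    day14 = c(above = sum(flow14$events > gate),
              below = sum(flow14$events <= gate))
  )
  add("diploid_increase_fisher", fisher_exact_2x2(tab[2:1, ], "greater"))
  rows[[length(rows) + 1L]] <- tibble::tibble(
    test = "diploid_frequency_change",
    statistic = NA_real_, df = NA_real_, p_value = NA_real_,
    estimate = frequency_change(est0, est14)
  )
  dplyr::bind_rows(rows)
}

#' Replay the replicate evolution experiment
#'
#' Evolves `n_tubes` replicate tubes under the scenario's protocol and
#' estimates each tube's start and end diploid fraction the way the
#' experiment does: 30,000-event hydroxyurea-arrested flow samples pushed
#' through [diploid_fraction()] (full closed loop, not simulator truth).
#'
#' @param config A [sim_config()]; its seed anchors per-tube sub-seeds.
#' @param n_tubes Number of replicate tubes (0 gives an empty table).
#' @param flow_events Events per flow sample.
#' @param escape_fraction Arrest-escape fraction used by both the
#'   generator and the estimator.
#' @return Tibble with one row per tube: `tube`, `d_start_true`,
#'   `d_end_true`, `d_start_est`, `d_end_est`, `delta_est`.
#' @export
replay_replicate_evolution <- function(config, n_tubes = 30L,
                                       flow_events = 30000L,
                                       escape_fraction = 0.10) {
  n_tubes <- as.integer(n_tubes)
  empty <- tibble::tibble(
    tube = integer(0), d_start_true = numeric(0), d_end_true = numeric(0),
    d_start_est = numeric(0), d_end_est = numeric(0), delta_est = numeric(0)
  )
  if (n_tubes == 0L) return(empty)
  rows <- vector("list", n_tubes)
  last_day <- config$protocol$n_days
  for (tube in seq_len(n_tubes)) {
    cfg <- config
    cfg$seed <- (config$seed + 7919L * tube) %% .Machine$integer.max
    evo <- simulate_evolution(cfg)
    t0 <- evo$diploid_fraction[evo$day == 0][1L]
    t1 <- evo$diploid_fraction[evo$day == last_day][1L]
    f0 <- generate_flow_sample(flow_events, t0, arrested = TRUE,
                               escape_fraction = escape_fraction)
    f1 <- generate_flow_sample(flow_events, t1, arrested = TRUE,
                               escape_fraction = escape_fraction)
    e0 <- diploid_fraction(f0, 100, escape_fraction)
    e1 <- diploid_fraction(f1, 100, escape_fraction)
    rows[[tube]] <- tibble::tibble(
      tube = tube, d_start_true = t0, d_end_true = t1,
      d_start_est = e0, d_end_est = e1,
      delta_est = frequency_change(e0, e1)
    )
  }
  dplyr::bind_rows(rows)
}
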