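#!/usr/bin/env Rscript
# Forward-simulate the three study designs (neutral mixture, cryptic
# frequency-dependent diploid advantage, late sweeper) under daily 1:101
# serial transfer and record the daily strain frequencies.

library(ploidyflux)

seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L
dir.create("results", showWarnings = FALSE)

for (scen in c("neutral", "diploid_fds", "late_sweeper")) {
  cfg <- scenario_config(scen, seed = seed)
  evo <- simulate_evolution(cfg)
  path <- sprintf("results/evolution_%s.tsv", scen)
  write_flux_tsv(evo, path,
                 provenance = sprintf("scenario=%s seed=%d hash=%s",
                                      scen, seed, rlang::hash(cfg)))
  first <- evo$diploid_fraction[1]
  last <- tail(evo$diploid_fraction, 1)
  message(sprintf(
    "%-12s diploid fraction day 0 -> day %d: %.3f -> %.3f  (%s)",
    scen, cfg$protocol$n_days, first, last, path
  ))
}

message("In the diploid_fds design the diploids rise from 1% despite equal ",
        "monoculture growth rates: the advantage exists only when rare.")
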