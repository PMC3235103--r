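Package: ploidyflux
Title: Ploidy Dynamics in Serial-Transfer Batch Culture: Simulation and Fitness Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the invasion of diploids into haploid yeast
    populations under daily serial-transfer batch culture. Provides a seeded
    forward simulator of feast-famine growth cycles with dilution bottlenecks
    and optional frequency-dependent selection; prolate-spheroid cell-geometry
    descriptors (volume, surface area, eccentricity, SA/V); growth-curve
    analysis (maximal log-OD slope via local regression, biomass production);
    Malthusian competitive-fitness estimation from fluorescent competition
    assays; flow-cytometry ploidy calling by exact one-dimensional k-means and
    hydroxyurea-arrest diploid-fraction estimation; aneuploidy screening from
    per-chromosome coverage ratios; and the classical inferential procedures
    (Welch t, partial correlation, Fisher exact, regression F, balanced
    two-way ANOVA) implemented from first principles so every result is
    oracle-checkable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    rlang
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
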