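---
title: "Ploidy invasion dynamics in serial-transfer batch culture: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ploidy invasion dynamics in serial-transfer batch culture: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ploidyflux)
```

## The scientific problem

Diploid lineages arising spontaneously inside asexual haploid yeast
populations can invade and eventually fix under daily serial-transfer
batch culture, even when every standard fitness assay — lag phase, maximal
growth rate, biomass production, and competition against a marked common
competitor — detects no diploid advantage. `ploidyflux` packages the full
quantitative toolkit needed to study this puzzle: a seeded forward
simulator of the batch-culture system, the cell-geometry, growth-curve,
competition-fitness and flow-cytometry analyses applied to it, and the
classical inferential procedures, all implemented so that every number can
be checked against an independent oracle.

The central modelling idea is *negative frequency-dependent selection*: a
Malthusian advantage proportional to `1 - f` (with `f` the strain's own
frequency) is invisible in monoculture (`f = 1`) and in symmetric
head-to-head assays, yet drives a rare lineage upward until effective
growth rates equalise. The package's `diploid_fds` scenario reproduces
exactly this dissociation between assays and population dynamics.

## The batch-culture growth model

One transfer cycle (`simulate_cycle()`) is modelled in three phases per
strain *i*:

1. **Lag** — no growth for the first `lag_i` hours after transfer
   (default 1.5 h).
2. **Exponential growth** — per-hour Malthusian rate
   `r_i + b_i (1 - f_i)`, where `r_i` is the monoculture maximum
   (default 0.46 h⁻¹, a 90-minute doubling), `b_i` the
   frequency-dependence coefficient (default 0), and `f_i` the strain's
   current frequency. `b_i > 0` is an advantage when rare. With two
   strains both carrying `b`, effective rates equalise at frequency
   `b_1/(b_1 + b_2)`, producing rise-then-plateau dynamics.
3. **Hard stop** — growth ceases the instant the shared glucose pool is
   exhausted. No diauxic/ethanol phase is modelled: respiration of
   fermentation by-products is slow relative to the 24 h cycle and is
   deliberately out of scope, so 24 h biomass is fermentative only.

Glucose accounting is exact: fresh medium carries 2% w/v glucose (the
standard rich-medium recipe; the concentration is assumed, not measured),
and each new cell of strain *i* consumes `yield_per_cell_i` grams
(default `1e-10` g for the 65 µm³ reference haploid, scaled
proportionally with cell volume, so a culture of fewer, larger diploids
consumes glucose at the same bulk rate — matching the observation that
ploidies deplete glucose equally despite different cell counts). The
integrator freezes rates within 0.25 h sub-steps (growth is then exactly
exponential within a step) and solves the glucose-exhaustion instant
inside the final step by root finding, so with frequency-independent
rates the trajectory is exact rather than discretised.

The daily bottleneck (`bottleneck()`) thins each strain binomially with
probability `1/D` (`D = 101`). Independent binomial draws per strain
stand in for joint hypergeometric sampling; at the 10⁷–10⁹ cell scale of
these cultures the distinction is negligible. A `D`-fold dilution implies
`log2(D) = 6.658` doublings per day once the culture re-saturates, which
is the generation accounting used throughout (14 days → 93 generations).

Optical density is proportional to biovolume density, calibrated so a
saturated reference haploid culture reads OD 1.3 (a typical plate-reader
ceiling on rich medium), with readings floored at the 0.04 instrument
detection limit. Diploidization (spontaneous whole-genome doubling) is
applied per cycle with per-cell probability `1 - (1 - rate)^6.658`;
converted cells join the first diploid strain in the configuration.

## What the generators emulate — and what they do not

* `generate_od_curve()`: 48 h plate-reader curves read every 15 min with
  i.i.d. Gaussian read noise (default sd 0.005 OD) — no well-edge
  effects, no condensation artefacts, no run-to-run medium variation.
* `generate_flow_sample()`: DNA-content fluorescence as Gaussian peaks
  with 8% CV at `c`/`2c` for haploids and `2c`/`4c` for diploids; under
  hydroxyurea arrest each ploidy collapses to its G1 peak except a 10%
  escape fraction left at G2. Real histograms carry debris, doublets and
  S-phase shoulders that are assumed gated out upstream.
* `generate_cell_measurements()`: log-normal major axes calibrated so the
  expected prolate-spheroid volume equals the strain's target exactly
  (haploid 65 µm³, diploid 115 µm³ by default; the per-time-point
  analyses use 57.3 and 100.5 µm³), with independent width noise around
  the target eccentricity. No budding-cell or segmentation artefacts.
* `generate_competition_counts()`: binomial draws of 10,000 cells per day
  around the two-type selection model.

Passing tests therefore demonstrate correctness of the estimators under
these idealised error models, not robustness to instrument pathologies
absent from them.

## Estimators

**Cell geometry.** For a prolate spheroid with full axes `L ≥ W`:
`V = πLW²/6`, `e = sqrt(1 - (W/L)²)`, and with semi-axes `a = L/2`,
`b = W/2`: `SA = 2πb²(1 + (a/(be)) asin e)`, with the removable `e → 0`
singularity handled by series so the sphere value `πW²` is returned
continuously. Transposed axes (`W > L`, a manual-ellipse slip) are
swapped with a warning rather than rejected. Both formulas agree with
numeric surface/solid-of-revolution quadrature to 1e-9/1e-6 relative
over the biological axis range, and every computed cell satisfies the
isoperimetric bound `SA ≥ (36π)^{1/3} V^{2/3}`.

**Growth curves.** `max_growth_rate()` natural-log-transforms OD,
excludes readings at or below the 0.04 floor (rather than imputing
them), fits a degree-2 loess with tricube weights (span 0.3 of the
points), and reports the maximum first derivative of the smooth on a
0.05 h grid. The "derivative of the smooth" reading was chosen over
"slope between knots"; both are available interpretations of
steepest-slope fitting and differ negligibly on 15-min grids. The
estimator is exact to <0.5% on pure exponentials across spans 0.2–0.5
and is scale-invariant in OD. Its known limitation: when the true
maximal slope sits at the *edge* of the read window (e.g. a logistic
already at full tilt at t = 0), the one-sided local fit overshoots by
O(h²) — about +5% for a 24 h window at span 0.3 and +15% for a 48 h
window. Validation therefore uses one 24 h transfer cycle, the
fitness-relevant window; comparative analyses (ploidy A vs B on the same
plate) are unaffected because the bias is shared. `biomass_production()`
is the OD at 24 h minus the OD at the start, nearest reading within
±0.25 h, no interpolation. Lag duration is *not* estimated from OD (it
occurs below the detection floor); lag is exercised only through the
glucose-depletion series.

**Competition fitness.** The non-fluorescent fraction follows
`p(T) = p0 e^{mT} / (p0 e^{mT} + 1 - p0)`, i.e. logit p is affine in
generations with slope `m`. `fit_competition()` minimises squared error
on the *fraction* scale (what `nls` on the model formula does) by
Gauss–Newton with the analytic Jacobian, initialised from the exact
logit-linear regression (counts clipped to `[1/(n+1), n/(n+1)]`),
converging when the parameter step drops below 1e-10. The logit-affine
form doubles as the independent oracle in tests: noiseless data are
recovered to 1e-6, sign flips exactly under fluor/non-fluor relabelling,
and the fit is invariant to scaling all counts.

**Ploidy calling.** `g1_peak()` takes the lowest mode above 10% of the
density maximum (Gaussian kernel, Silverman bandwidth). `call_ploidy()`
solves 1-D k-means (k = 2) *exactly* by enumerating all sorted-threshold
splits — the optimal 1-D partition is always such a split — avoiding any
initialisation sensitivity; the lower-centroid cluster is haploid, and
the WSS drop from k = 1 to k = 2 is reported descriptively.
`diploid_fraction()` gates arrested samples at 1.5× the haploid G1 peak
(the midpoint of the `c`/`2c` peaks; the original gates were manual) and
inverts the escape model `raw = d + (1 - d)·esc`, assuming escaped cells
sit at their G2 position. With 8% peak CV the gate misclassifies only
the ~3σ tails (≈0.1% of events). `coverage_ratios()` flags chromosomes
whose relative coverage leaves the 0.6–1.4 band, midway between the
euploid 1.0 and the 1.5×/2× shifts a whole-chromosome gain produces in
diploids/haploids.

**Inference.** Welch t (with Welch–Satterthwaite fractional df), partial
correlation via residual-on-residual correlation, Fisher's exact 2×2 by
hypergeometric enumeration with the probability-ordering two-sided rule,
simple-regression F, and balanced two-way ANOVA by orthogonal
sums of squares are all written from the defining formulas; the test
suite cross-checks each against an independent route (reference
implementations, brute-force enumeration, explicit projection matrices).
Degenerate inputs follow documented conventions: identical samples give
`t = 0, p = 1`; exact fits report a floor p-value with an `"exact fit"`
flag; df = 1 comparisons are permitted with a low-power message;
unbalanced ANOVA designs are refused with direction to a regression
formulation. No multiple-testing correction is applied anywhere.

## Numerical choices

* Cycle integration sub-step 0.25 h; rates refresh each sub-step, so
  frequency-dependent trajectories carry O(dt) error (≈1e-4 in daily
  logit increments at the default parameters); exhaustion times are
  root-found to 1e-12.
* Competition Gauss–Newton: 200-iteration cap, step clamped so
  `p0 ∈ (1e-12, 1 - 1e-12)`; non-convergence errors with diagnostics.
* k-means ties in WSS resolve to the first (lowest) split; identical
  peaks error as "no separation".
* `rbinom()` falls back to a normal approximation only above 2³¹ − 1
  cells, beyond any default configuration.
* Loess evaluation grid 0.05 h; derivative by first differences of the
  smooth on that grid.

## Validation problem sizes

The shipped checks use: a 50×50 (L, W) grid against quadrature oracles;
200 binomial competition assays (10,000 cells/day) at m = 0.05; 20 noisy
logistic curves on a 24 h window; a diploid-mixture sweep 0→1 in steps
of 0.1 with three 30,000-event arrested samples per point; exhaustive
Fisher enumeration over all 2×2 tables with cells ≤ 6; and 50 seeded
runs of the `diploid_fds` scenario (14 daily transfers; five replicate
growth wells per ploidy). These sizes keep the full suite to a few
minutes while leaving Monte-Carlo margins of ≥3 standard errors on every
stochastic assertion.

## Known limitations

* The frequency-dependence term is linear in `1 - f`; no mechanistic
  basis (cross-feeding, spatial refuge) is modelled, and other
  functional forms would change plateau positions.
* No diauxic shift: post-fermentative growth that could add biomass
  between hour ~20 and 24 is absent, so simulated biomass slightly
  understates cultures that respire ethanol late in the cycle.
* Absolute growth-rate estimates carry small positive bias near the
  lag→exponential and exponential→saturation corners of hard-stop
  curves (and at read-window edges, above); ploidy *comparisons* share
  and cancel this bias.
* The arrest-escape correction assumes the escape fraction is known and
  frequency-independent; a mis-specified escape fraction biases the
  estimated diploid fraction by `(esc_true - esc_assumed)/(1 - esc)` at
  low diploid frequency.
* Strains are fully asexual by construction: no mating, meiosis, or
  ploidy reduction, and aneuploidy screening is read-count based only.
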