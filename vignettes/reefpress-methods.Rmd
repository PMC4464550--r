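---
title: "Methods: tide-pool reef community analysis with reefpress"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tide-pool reef community analysis with reefpress}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

reefpress reproduces, as tested and reusable code, the quantitative chain
of a tide-pool reef study contrasting wave-exposed open pools with
isolated closed pools. This vignette documents the models, the tunable
parameters and their defaults, what the synthetic-data generator does and
does not emulate, the numerical choices, and the package's known limits.

## Sampling designs and their models

**Belt-transect censuses.** Divers count and size fish over 40 m²
(20 × 2 m) strips. The generator draws per-transect, per-species counts
from a negative binomial with habitat-specific mean and dispersion `k`
(default 5), because visual-census counts are overdispersed relative to
Poisson; `k = Inf` is an explicit Poisson token. Total lengths are
lognormal around the species' mean length with its CV, truncated at 1 cm —
lengths are positive and right-skewed, and divers record them as point
estimates, so no observation-error model is layered on top. Transects
where nothing was seen are kept as placeholder rows: a zero observation is
data, and dropping it would bias density estimates upward.

**Video feeding plots.** 2 m² areas filmed for 10 analyzed minutes.
Foragers arrive with the same count model scaled by plot/transect area;
each individual's bite total is Poisson around the habitat × species rate.
Feeding pressure is bites × body mass (kg) summed within a plot, kept in
the field unit (bites·kg per 2 m² × 10 min) so outputs are directly
comparable with published figures; `pressure_per_m2_min()` converts.
Species, group and habitat pressures are means over plots of within-plot
contributions — the plot, not the fish, is the sampling unit, which is
also why the habitat contrast runs a t-test on square-root transformed
plot values and bootstraps by resampling plots.

**Point intercepts.** 50 random points per 25 × 25 cm photoquadrat (five
per plot) or per stomach spread, one multinomial draw per set. Cover is
`100 * n_c / n_scored` with "unscorable" points removed from the
denominator — the point-count-software convention. Diet profiles are also
reported renormalized after removing sediment and detritus, to expose the
algal fraction. Aggregation is set → plot → habitat (means of means), with
the per-set matrix also exposed for analyses that want to pool quadrats.

**Herbivory assays.** Each of 13 trials (run over 3 days) offers seven
macroalgae of roughly equal initial mass (default 10 g) on a rope, beside
a caged control rope that measures handling/hydrodynamic loss (default 8%
with 2% multiplicative noise). The printed form of the consumption formula
in the field literature, `[Wr_i × Wc_F / Wc_i] / Wr_F`, is the
expected-over-observed remaining-mass ratio and exceeds 1 under
consumption; the quantity a "proportion consumed" requires is
`1 − Wr_F / (Wr_i · Wc_F / Wc_i)`, which is what `consumed_proportion()`
returns (the ratio form stays available via `method = "as_printed"` for
audit). Negative proportions — apparent growth — are returned flagged, not
clipped. The generator links bites to mass through a per-bite removal
parameter (default 0.05 g with lognormal noise); no such link is measured
in the field, so this is a simulation device only.

**Selectivity.** Strauss' linear index L = r_i − p_i per assay, with r_i
the alga's share of the species' bites and p_i its share of the *initial*
offered mass. Per species × alga, observed per-assay L values are averaged
and a percentile bootstrap CI (default 1,000 iterations) is taken by
resampling assays with replacement — the assay is the replicate, so it is
the resampling unit (resampling pooled bites would pretend bites are
independent across trials). CI entirely above 0 ⇒ selected; below ⇒
avoided; else neutral. Assays where the species took no bites leave r
undefined and are skipped with a reported count, not failed. Fewer than
two contributing assays yields a flagged, unclassified result.

**Algal turfs.** 10 × 10 cm scrapes, five per pool, two pools per habitat
(20 samples). Total dry weight is lognormal around the habitat mean (open
3× closed by default, mirroring the direction of published contrasts) and
is split across turf taxa by gamma-perturbed habitat shares. Cryptofauna
counts are Poisson around `max(intercept + slope · weight, 0)` (negative
means floored with a warning) with lognormal rate noise; the analysis
stage regresses total cryptofauna on total dry weight by OLS.

## Community statistics

These are implemented natively (they are the analysis core, and native
implementations are deterministic and oracle-testable); the test suite
cross-checks them against `vegan` and `stats` on fixtures.

* **Bray–Curtis**: `sum|x−y| / sum(x+y)`; undefined (and flagged) for two
  all-zero samples.
* **ANOSIM**: all off-diagonal dissimilarities are ranked with average
  ranks on ties; `R = (mean between-group rank − mean within-group rank) /
  (n(n−1)/4)`. The n(n−1)/4 scaling is what bounds R in [−1, 1] (two
  groups of two with all between-distances above all within-distances give
  exactly R = 1). p-values use the (1 + exceedances)/(n_perm + 1)
  estimator, never zero, with 999 permutations by default; for small n an
  `exhaustive = TRUE` mode enumerates every distinct labeling.
* **Ordination**: the field convention for display is nonmetric MDS, but
  its stress minimization is iterative and starting-point dependent, so
  the package substitutes metric PCoA (Gower double-centering,
  eigendecomposition, coordinates scaled by √eigenvalue) — deterministic,
  testable against PCA on Euclidean input, and recorded as a substitution
  in the run manifest. Negative eigenvalues (semi-metric input) are
  reported, never silently dropped. PCA is a column-centered covariance
  eigendecomposition; any arcsine transform is applied upstream.
* **Friedman**: χ² = 12/(nk(k+1))·ΣR_j² − 3n(k+1) on k−1 df, average ranks
  on ties and no tie correction (so the statistic matches the textbook
  formula exactly; `stats::friedman.test` differs on tied data because it
  corrects for ties). The post hoc is the Siegel–Castellan rank-sum
  criterion |R_j − R_l| > z_(1−α/(k(k−1)))·√(nk(k+1)/6), a
  Bonferroni-style family control, chosen because no more specific
  procedure is standard for this design.
* **Ordinary fits** (t-tests, one-way ANOVA, OLS) delegate to `stats`;
  square-root transforms are applied on request and recorded in the
  result.

## Randomness and determinism

One root seed lives in the scenario config. Every generated table and
every resampling routine derives its own stream from `(seed, label)` via a
rolling byte hash, so adding a generator or reordering stages never shifts
another stream's draws. Two runs with identical config and seed produce
byte-identical CSV bundles; the manifest records the seed and per-file MD5
checksums.

## What the generator does and does not emulate

It reproduces the *statistical* structure the analyses assume: habitat
differences enter only through configured rates (abundance means, bite
rates, cover and diet multinomials, turf means), and the default scenario
is pinned to the field design sizes — 153 transects (closed 64, open 59,
lagoon 20, outer reef 10), 45 + 40 video plots, five 50-point quadrats per
plot, 13 assay trials, 20 turf scrapes — with cover profiles anchored to
published habitat percentages (e.g. 51% non-calcified turf and 31%
sediment in closed pools) and the expected closed:open pressure ratio
calibrated to 20 via `set_pressure_ratio()`. It does not simulate tides,
predator avoidance, diver behavior, spatial autocorrelation within pools,
or length-estimation error. Passing tests therefore demonstrate that the
estimators recover known generating parameters under the design's sample
sizes — not that field data meet the generators' distributional
assumptions.

## Numerical choices and degenerate inputs

* Percentile bootstrap CIs use `stats::quantile` type 7 on the resampled
  means; degenerate inputs (all values equal) collapse the CI to a point.
* A zero-pressure denominator habitat flags the ratio undefined rather
  than returning Inf.
* An all-unscorable point set returns NA covers with a flag; renormalized
  diet profiles drop stomachs left empty after exclusion and report how
  many.
* Constant-predictor regressions are flagged undefined; constant-response
  regressions return slope 0 and R² = 0 exactly.
* Strauss sums are asserted to 1e-12; dissimilarity symmetry to 1e-12;
  PCoA eigenvalue positivity uses a relative 1e-9 cutoff.
* Validation failures carry condition classes
  (`reefpress_validation_error`, `reefpress_config_error`) and name the
  offending table, row and column.

## Problem sizes used by the test suite

The simulation-based checks run at sizes chosen to make Monte-Carlo error
small relative to the tolerance while keeping the default suite quick:
1,000 transects/quadrats for unbiasedness checks (3 SE bands), 1,000
replicates × 1,000 bootstrap iterations for CI coverage, 1,000 null
simulations × 999 permutations for ANOSIM calibration, 500 replicates for
pressure-ratio coverage at the design's 45 + 40 plots, 100 seeds for the
end-to-end selectivity recovery, and exhaustive enumeration for all
Friedman tables with n ≤ 3, k ≤ 3 and values in {1, 2, 3}.

## Known limitations

* The percentile bootstrap of a mean has finite-sample coverage below its
  nominal level for small replicate counts: for n i.i.d. normal values its
  coverage is approximately `P(|T_(n−1)| ≤ z_0.975 · √((n−1)/n))`, about
  91.6% at the design's 13 assays. The package implements the percentile
  method as the field convention prescribes and reports it as such; users
  needing calibrated small-sample intervals should increase replication or
  use a t-interval on the assay-level values.
* The same effect touches the pressure-ratio CI at 45 + 40 plots, where
  plot totals are strongly right-skewed (rare large fish dominate sparse
  2 m² plots); its realized coverage is a few points under 95%.
* ANOSIM p-values are permutation estimates with resolution 1/(n_perm+1).
* PCoA replaces nMDS for display; with strongly non-Euclidean
  dissimilarities the two can order configurations differently.
* The 37-category field vocabulary is not hard-coded: categories are
  data-driven via the config, and exclusion lists (e.g. transient fish
  schools removed from ordination) are configuration, not rules.
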