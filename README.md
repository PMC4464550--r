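# reefpress

Quantitative machinery for contrasting shallow tide-pool reef habitats —
for reef ecologists comparing wave-exposed ("open") pools that stay
connected to the ocean at low tide with isolated ("closed") pools. The
package covers the full analysis chain such a field study needs: fish
assemblage structure from belt-transect visual censuses, fish feeding
pressure on the benthos from remote-video plots, benthic and stomach
point-intercept cover, algal-turf biomass with its cryptofauna, and
multiple-choice herbivory assays with selectivity analysis. A seeded
synthetic-data generator emulates every sampling design, so the complete
pipeline runs and is tested end to end without any field data.

## The statistics at its core

* **Allometric biomass** — each censused fish of total length *L* (cm)
  converts to mass via the length–weight relationship *W = a·L^b* (g);
  densities and biomasses aggregate per 40 m² (20 × 2 m) belt transect and
  per functional group.
* **Feeding pressure** — for every fish recorded feeding in a 2 m² / 10 min
  video plot, bites × body mass (kg); plot totals are expressed as
  (bites × kg) / (2 m² × 10 min), the plot being the sampling unit. Habitat
  contrasts report the ratio of mean plot pressures with a percentile
  bootstrap CI (resampling plots) and a t-test on square-root transformed
  values.
* **Point-intercept cover** — 50 random points per photoquadrat or stomach
  spread; cover_c = 100·n_c / n_scored with unscorable points excluded from
  the denominator; arcsine-square-root transforms for Euclidean-distance
  ordination; diet profiles with and without the sediment/detritus
  fractions.
* **Herbivory assays** — consumption corrected by a caged autogenic
  control: consumed proportion = 1 − W_rF / (W_ri · W_cF / W_ci).
  Selectivity uses the Strauss linear selection index *L = r_i − p_i*
  (bite share minus offered-mass share), averaged over assays, with a
  1,000-iteration assay-level percentile bootstrap CI: CI > 0 ⇒ selected,
  CI < 0 ⇒ avoided, otherwise neutral.
* **Community statistics, implemented natively** — Bray–Curtis and
  Euclidean dissimilarities; ANOSIM with
  R = (r̄_B − r̄_W) / (n(n−1)/4) and permutation p-values
  (1 + exceedances)/(n_perm + 1), plus exact enumeration for small n;
  principal coordinates analysis (Gower double-centering); PCA; Friedman's
  χ² = 12/(nk(k+1))·ΣR_j² − 3n(k+1) with a Siegel–Castellan post hoc.

## Worked example

```r
library(reefpress)
cfg <- default_scenario(seed = 7)     # the study's sampling design, seeded
tables <- simulate_tables(cfg)        # censuses, plots, quadrats, assays...

pp <- plot_pressure(tables$video_plots, tables$length_weight)
habitat_contrast(pp, "closed", "open", seed = 7)
#> Pressure ratio 34.1 (95% CI 13-130), t = 4.85, p = 1.35e-05

L <- strauss_assays(tables$assays)
head(bootstrap_selectivity(L, seed = 7), 3)
#>                species                      alga  mean_L  ci_low ci_high classification
#> 1 Acanthurus chirurgus           Digenea simplex  0.4586  0.4456  0.4728       selected
#> 2 Acanthurus chirurgus             Sargassum sp. -0.0396 -0.0497 -0.0299        avoided
#> 3 Acanthurus chirurgus Dictyopteris plagiogramma -0.0601 -0.0675 -0.0523       avoided
```

The contrast says mean plot pressure in closed pools is ~34× the open-pool
mean in this realization (the scenario's expected ratio is 20; single
realizations of 45 + 40 skewed plot totals scatter widely, which the wide
CI reflects). The selectivity table classifies *Digenea simplex* — 60% of
assay bites against an offered-mass share of 1/7 — as selected, and the
other algae as avoided or neutral.

`run_pipeline(cfg, out_dir = "bundle")` executes every stage and writes a
CSV bundle (transect summaries, ANOSIM/ordination results, cover tables,
pressure breakdowns, consumption, selectivity, Friedman tests, diet
profiles) plus a `manifest.json` with the seed and file checksums; two runs
with the same config and seed are byte-identical. A thin command-line
wrapper lives at `inst/cli/reefpress.R`.

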