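---
title: "Preparing and auditing LGM climate layers: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Preparing and auditing LGM climate layers: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glacialclim)
```

## The problem

Ecological niche models projected onto the Last Glacial Maximum (LGM,
~21 ka) are trained on bioclimatic layers derived from general
circulation model (GCM) output. Different GCMs disagree — strongly, and
in spatially structured ways — so the choice of models and of
bioclimatic variables drives the biological conclusions. `glacialclim`
implements the full layer-preparation pipeline (long-term means, unit
conversion, change-factor downscaling by ordinary kriging, the 19
bioclimatic variables) together with the audit statistics that quantify
where and how an ensemble of GCMs disagrees (per-cell spread maps,
agreement masks, latitudinal profiles, correlation structure and
hierarchical model grouping).

## The downscaling model

Each GCM supplies monthly climatologies of `tas`, `tasmax`, `tasmin`
(Kelvin) and `pr` (precipitation flux) for a modern control and the LGM
scenario, on its native 1–4° grid. Preparation proceeds in three
steps (the change-factor, or delta, method):

1. **Trends at native resolution.** Temperature trends are differences
   `LGM − modern` per month and cell. Precipitation trends are relative
   anomalies `(LGM − modern)/modern`, which preserve spatial pattern
   for a positive, heavy-tailed variable.
2. **Interpolation to 0.5°.** The trend and the modern climatology are
   each interpolated to the common 0.5° grid by ordinary kriging from
   the 12 nearest observations, under a spherical variogram fitted to
   the omnidirectional sample variogram of each monthly surface. The
   spherical model reaches its sill exactly at the range, matching the
   finite decay of spatial autocorrelation in climate fields.
3. **Reconstruction.** `LGM = modern + trend` (temperature) or
   `LGM = modern × (1 + trend)` (precipitation, clipped at zero).

Interpolating the *trend* rather than the raw LGM field keeps the
reconstructed past coherent with the interpolated modern climatology:
when the two scenarios coincide, the reconstruction is bit-identical to
the interpolated modern layer (a property the test suite asserts).

### Numerical choices

* **Distances** are Euclidean in degrees on (lon, lat) — the default of
  the unprojected-coordinate geostatistics toolchain this package
  mirrors. A haversine option exists behind the `metric` argument.
  Neither metric wraps across the dateline; the two edges of a global
  grid are treated as far apart, exactly as in the mirrored toolchain.
* **Sample variograms** use 15 equal-width lag bins up to one third of
  the domain-bounding-box diagonal. On dense grids the pair scan is
  quadratic, so point sets above 3,000 are subsampled once,
  reproducibly, before binning — standard practice for variogram
  estimation on gridded data; the fit is insensitive to it.
* **Fitting** is weighted least squares with weights `N_h / h²`
  (pair count over squared lag), bounded below by zero for nugget and
  partial sill. Non-convergence falls back to the method-of-moments
  starting values with `converged = FALSE`; a flat (pure-nugget) sample
  variogram short-circuits with a warning.
* **Kriging ties** in the 12-nearest-neighbour search are broken by
  (lat, lon) lexicographic order, making predictions deterministic.
  Duplicate observation locations are averaged. A singular local system
  masks the cell and is counted. When the fitted variogram is entirely
  flat (total sill ≈ 0, e.g. kriging an identically-zero trend field)
  the ordinary-kriging system is singular *by construction*; the
  predictor then degrades to the neighbourhood mean, which is the
  correct limit (all observations are interchangeable) and preserves
  the exactness of the change-factor round trip.
* **Zero-modern precipitation.** The ratio trend is undefined where the
  modern climate is bone-dry. Where both scenarios are 0 the trend is
  0; where only the modern is 0 the ratio is computed against a floor
  of 0.1 mm/month and the cell is flagged. Reconstructed precipitation
  below zero (interpolation overshoot) is clipped to 0 and counted.

### Alternative interpolators and the accuracy benchmark

For the accuracy comparison the package also provides inverse distance
weighting (power 2, same 12-neighbour stencil as the kriging), exact
thin-plate splines, and a 12th-degree polynomial trend surface fitted
on orthogonalized terms (raw degree-12 monomials in degrees are
numerically unusable). Natural-neighbour interpolation has no reliable
implementation available to this package and is feature-flagged out;
the benchmark runs with whichever methods are present.

Thin-plate splines on more than ~1,500 points are solved by a partition
of unity: exact local splines on overlapping 36° tiles blended with
cosine-squared weights. The surface still reproduces every observation
(asserted to 1e−6 in the tests) at a small fraction of the dense-system
cost, which would otherwise need a ~16,000² solve for a global 2° grid.

`mse_benchmark()` scores each method against a reference layer by the
mean square error over `n_points` cells drawn without replacement,
repeated `n_reps` times (defaults 5,000 and 1,000, the full-scale
design; the packaged tests run 500 × 200 to stay fast). On fields
generated from a known spherical covariance, kriging attains the lowest
median MSE — the package asserts this, and the cross-method Pearson
correlations of the resulting surfaces (≥ 0.98 for the temperature-like
configuration, ≥ 0.96 for the precipitation-like one).

## Bioclimatic variables

`compute_bioclim()` derives BIO1–BIO19 from the downscaled monthly
layers following the standard worldclim-lineage equations, with one
deliberate deviation: **BIO1 is the annual mean of the raw `tas`
variable**, not the midpoint of `tasmax` and `tasmin` — GCMs simulate
`tas` directly, and the midpoint can differ by degrees.

Quarters are any 3 consecutive calendar months with December–January
wrap-around; ties (e.g. a constant climate) resolve to the earliest
start month. BIO4 uses the sample (n−1) standard deviation × 100;
BIO15 uses the sample SD over `1 + mean` so rain-free cells stay
finite. Both denominators are switchable (`sample_sd`, `bio15_offset`)
and recorded in the stack's attributes, since the reference lineage is
ambiguous about them. BIO3 is masked where the annual range BIO7 is
zero. Any cell with a non-finite input month is masked throughout.

## Ensemble agreement statistics

With all models' stacks aligned on the 0.5° grid
(`ensemble_cube()`), per-cell agreement is summarized two ways:

* `ensemble_sd()` — the sample (n−1) standard deviation across models:
  absolute spread, in the variable's units.
* `ensemble_qcd()` — the quartile coefficient of dispersion
  `(q3 − q1)/(q3 + q1)` with type-7 quartiles: relative spread.
  The ratio is meaningless around 0 °C and for sub-zero quartiles, so
  Celsius-scale variables are shifted to Kelvin before the quartiles;
  the shift is recorded in the result and cells whose shifted
  `q3 + q1` is still non-positive are masked and counted. With nine
  models the quartile estimator is visible in the result, hence the
  explicit type-7 declaration.

`agreement_mask()` marks cells where the QCD stays below 0.5 for all
19 variables; `zonal_profile()` and `region_summary()` aggregate any
map by latitude band or by a user-supplied labelled region mask (the
generic stand-in for ecoregion polygons, whose acquisition is out of
scope).

## Model grouping

`pairwise_model_correlation()` computes Pearson r between each model
pair across all shared unmasked cells, per variable. Cells are weighted
uniformly — flat pixel arrays, as in the workflow this package mirrors;
an equal-angle grid oversamples high latitudes, so area weighting is a
reasonable alternative a user can apply by subsetting cells.
`cluster_models()` clusters on the distance `d = 1 − r` with complete
linkage (the correlation-distance convention of the clustering library
this mirrors, which names the function but not its settings) and cuts
the tree at k = 4. Labels are renumbered by first appearance in the
model roster so tables are reproducible; `cluster_table()` assembles
the models × variables group table, and `correlation_summary()` the
long-format correlations with families (temperature BIO1–BIO11,
precipitation BIO12–BIO19) and 1.5 × IQR outliers.

Where a single all-variable grouping is wanted, the package averages
the 19 per-variable distance matrices. Stacking all layers into one
correlation would weight variables by their variance; averaging
distances weights variables equally, which matches how the per-variable
tables are read. Both views are available (pass one matrix or a list).

## The synthetic ensemble generator

Real multi-century GCM archives are not reproducible at desk scale, so
`generate_pseudo_gcm_ensemble()` plants the structure the audit is
supposed to find:

* a deterministic background climatology (latitudinal temperature
  gradient with hemispherically phased seasonality; a tropical
  precipitation peak), cooled and dried under the `lgm` scenario;
* per-group and per-model Gaussian random fields with spherical
  covariance (simulated by circulant embedding, exact for this
  compactly supported model up to clamping of negligible negative
  spectral mass), entering as an annual-mean deviation, a
  zero-annual-mean seasonal-amplitude deviation, and a group-structured
  diurnal half-range — so mean-state *and* seasonality/range variables
  (BIO2, BIO3, BIO4, BIO7) all carry the planted partition;
* a latitude-dependent disagreement amplitude: logistic in |lat| with
  midpoint 35°, rising poleward for temperature (0.8 → 5.8 °C) and
  towards the tropics for precipitation (4 → 40 mm/month). Because
  every stochastic deviation is multiplied by this amplitude, the
  ensemble SD of annual temperature must increase poleward and that of
  annual precipitation must peak in the tropics — the qualitative
  pattern the audit statistics detect, guaranteed by construction.

Defaults are nine models in four planted groups of sizes 1/2/3/3 with
within-group noise at 10% of the group signal, mirroring the ensemble
size and grouping granularity of the study design this package
supports. What the generator does *not* emulate: GCM physics, ice
sheets, teleconnections, month-to-month weather persistence, or
realistic land/sea masks. Passing tests therefore demonstrate that the
pipeline's algebra and statistics are correct and that planted signal
is recovered — not that any real GCM ensemble has this structure.

## Problem sizes and determinism

The packaged tests run on deliberately modest sizes: 4° global grids
for ensemble work, a 2° → 0.5° regional domain for the change-factor
round trip, 1° → 0.5° sub-grids for the MSE benchmark, and 2° → 1°
global surfaces for the cross-method correlation checks; the
acceptance script runs the full 2° → 0.5° global comparison. Every
stochastic step takes an explicit integer seed and restores the
caller's RNG state, so identical inputs give bit-identical outputs.

## Known limitations

* Distances ignore the dateline and meridian convergence unless the
  haversine option is chosen; at 0.5° this mirrors the reference
  toolchain but is not a spherical treatment.
* No land/sea or ice masking is imposed anywhere; if source grids
  disagree about masks, cells are handled by the missing-data rules,
  not harmonized.
* File interchange is plain annotated CSV; binary geospatial formats
  are out of scope for this build.
* The QCD's Kelvin shift makes temperature QCD values depend on the
  absolute scale chosen; the shift is recorded in the output for
  exactly this reason.
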