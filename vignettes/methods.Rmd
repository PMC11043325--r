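---
title: "Methods: reservoir standing-stock estimation in resstock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reservoir standing-stock estimation in resstock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`resstock` estimates total fish standing stock (kg) and secondary
production (kg y⁻¹) across a national dam inventory from legacy
rotenone-survey biomass densities. This vignette documents the model, its
assumptions, the tunable parameters, the synthetic-data generator, and
the numerical and design choices a maintainer should know about.

## Data model and cleaning

The inventory is a table of dams and their reservoirs: identifier, name,
state, WGS84 coordinates, completion year, storage volume (m³), maximum
discharge (m³ s⁻¹), and surface area (ha). Three cleaning rules run in a
fixed order:

1. **Deduplication.** Some reservoirs are impounded by several dams and
   appear once per dam. Rows sharing an identity key — case-folded,
   punctuation-stripped name plus state — collapse to the row with the
   largest storage volume (the main dam). Rows without names key on their
   id. This key is a documented stand-in; any inventory with an explicit
   reservoir-group id can be pre-keyed instead.
2. **Natural lakes.** Very large natural lakes with small regulating dams
   are not reservoirs and would dominate the area scale-up. Removal is
   flag- or list-driven (seeded with "Lake Superior"), never heuristic.
3. **Area basis.** Rows with neither surface area nor storage volume are
   dropped: nothing supports an area estimate for them.

The accounting identity `rows out + removals = rows in` is enforced by
test, and cleaning is idempotent.

Missing areas are then filled from an OLS fit of ln(area) on ln(volume)
over complete records — morphometric area–volume relations are power laws
to good approximation — with a median area/volume-ratio fallback below 10
complete pairs (a regression on fewer points is not worth trusting).
Observed areas are never modified; filled rows carry an
`area_approximated` flag.

Reservoirs join level-II ecoregions by point-in-polygon
(`mgcv::in.out`). A point on a shared polygon edge goes to the first
polygon in layer order — deterministic and documented; with a tiled layer
this affects only measure-zero boundary points. Records without
coordinates, or outside all polygons, keep a missing ecoregion and are
counted, not dropped.

## Recovery correction

Rotenone kills nearly all fish present, but not all carcasses are
recovered; published species recovery rates imply the multiplicative
correction 1.773056 applied to every raw density. The constant lives in
configuration; its literature derivation is cited upstream and not
recomputed here. The correction is exact, linear, and order-preserving —
properties under test.

## Classification schemas

Five schemas of ascending complexity place every reservoir in a class:

| schema | definition | label form |
|---|---|---|
| 1 | single class | `all` |
| 2 | k-means, k = 2, standardized ln(volume + 1) | small / large |
| 3 | k-means, k = 4, globally standardized ln(volume + 1), ln(discharge + 1) | size–flow |
| 4 | level-II ecoregion | ecoregion label |
| 5 | within-ecoregion k-means, k = 4, within-ecoregion standardization | ecoregion–size–flow |

Only schemas 4–5 and the single-class schema are fully pinned down by the
classification system's description; schemas 2–3 are defined here as the
natural ecoregion-free ablations of schema 5 and are config-swappable —
a divergence risk against any other implementation, flagged prominently.
"Scaled" is read as z-scoring; for schema 5 the covariates are
standardized *within* each ecoregion (each clustering acts on its own
stratum), a genuinely open choice documented here.

Clustering uses `stats::kmeans` (Hartigan–Wong) with 25 seeded restarts;
empty-cluster failures re-seed that attempt. When k equals the number of
distinct points the optimum (one point per cluster, SSE 0) is returned
directly. Cluster labels come from centroid ranks: the lower half of the
centroid volumes is "small", the lower half of centroid discharges "low";
ties break by the other axis and then by cluster index, so labelling is
deterministic even for identical centroids. Records missing the
covariates a schema needs get the reserved label `unclassified`;
ecoregions with fewer eligible reservoirs than k form a single
`eco|all` class rather than a degenerate clustering.

## The density GAMM

Corrected densities are modelled with a Gamma/log-link generalized
additive mixed model:

> ln E[density] = s(age) + s(year) + class + s₍class₎(age) + u(reservoir)

with thin-plate smooths (basis dimension `k_basis = 10`), a separate age
smooth per class (factor-smooth interaction), and a ridge-penalized
reservoir random-intercept smooth, all fitted by `mgcv::gam` with REML
smoothness selection. The Gamma family matches the strictly positive,
right-skewed, multiplicative-error character of biomass densities; zeros
are outside Gamma support and are excluded (and counted) during model
preparation, as are rows with missing age, year, or class, and classes
with fewer than `min_class_n = 5` surveys.

Degenerate inputs degrade gracefully rather than erroring: a single class
drops the factor-smooth block, a single reservoir drops the random
effect, and a covariate with too few distinct values enters linearly.
With `smooth = FALSE` every term enters linearly, which is the Gamma GLM
limit used by the IRLS oracle test. Two numerical fallbacks are
deliberate: an exactly constant response makes the REML criterion
degenerate inside mgcv, so the fitter retries with GCV smoothness
selection; and a perfect fit (deviance below 10⁻⁶ of the null deviance)
is accepted even when the optimizer's convergence flag is unset, since
the solution is exact.

### Standardization year and extrapolation

All densities are standardized by prediction at a common year, 1993,
removing noise from reservoirs sampled in different decades. Predictions
beyond the final empirical year advance the **year** term to the target
year but evaluate the **age** smooths at the final empirical year's ages,
never beyond the span they were fit on: penalized splines extrapolate
linearly from their boundary and small boundary-slope errors grow without
bound outside the data, whereas post-impoundment age effects (the
"trophic upsurge" spike) have dissipated at these ages. This choice was
made after observing, on synthetic data with known truth, that in-sample
class means recovered within ~7% while advancing ages 15 years past the
data inflated one class by ~12% through spline extrapolation alone.

Sampled reservoirs are predicted with their own random intercept;
class-level (population) predictions exclude the random-effect term. The
choice that unsampled reservoirs receive *class means of per-reservoir
predictions* (not class-level curve evaluations) keeps imputed densities
on the same scale as the sampled ones; with a log link the two differ by
Jensen terms.

## Scale-up, ensemble, production

Standing stock is exactly density × area (kg). Imputation provenance —
`model`, `class_mean`, `global_mean` — is recorded per reservoir, and
every cleaned reservoir appears exactly once per schema. Aggregations
keep an explicit `unassigned` bucket for missing states/ecoregions so
group totals always partition the national total. The "southern" region
defaults to the 22 survey-rich states and is configurable.

The five schema totals form an ensemble: mean and SE = sd/√5 "across
calculations". This is an uncertainty over *classification systems*, not
a sampling variance; it deliberately brackets the structural choice the
analysis is most sensitive to.

Production multiplies standing stock by a literature whole-community P/B
ratio: default `pb_mean = 1.30` y⁻¹ with interquartile range
`0.583–1.823` y⁻¹, consistent with the published regional production
figures relative to the published biomass totals. The per-reservoir
production IQR implied by a different part of the published record
(≈0.51/1.59) is mildly inconsistent with these; the defaults follow the
regional totals, and all three values are configuration, not constants.

## Validation

Independent-survey standing stocks validate the pipeline through a
mixed-effects regression of ln(observed) on ln(predicted) with the
classification schema as a random intercept (`lme4::lmer`, REML). Stocks
span several orders of magnitude, so the log–log scale is the default
(`log_scale = FALSE` switches to raw). Reported: slope with a Wald z test
against 1, Nakagawa-style marginal and conditional pseudo-R²
(σ²f / total and (σ²f + σ²r) / total, with σ²f the population variance of
the fixed-effect predictor), and the standardized-major-axis slope
sign(r)·sd(y)/sd(x) as a robustness companion. A single group reduces to
OLS with a warning; an exactly singular perfect fit recovers the
fixed-effect covariance from σ̂²(XᵀX)⁻¹ where `vcov` fails.

## The synthetic-data generator

The generator is first-class, tested code that emulates the statistical
structure the analysis assumes:

* **Covariates** — ln(volume) and ln(discharge) jointly normal
  (defaults: means 12 and 1, sds 2 and 1.5, correlation 0.7) with
  N(0, 0.5) per-ecoregion mean shifts; area (ha) = 10⁻⁴·V⁰·⁹·exp(N(0,
  0.3)), consistent with a mean depth of a few metres across the volume
  range.
* **Latent classes** — quadrants of the median-split clustering
  covariates, so the size–flow schemas can recover the generating
  partition; baseline densities 150/250/350/500 kg ha⁻¹ for
  small-low/small-high/large-low/large-high, within the range of
  rotenone-era reservoir surveys.
* **Dynamics** — a log-scale age effect α·age·exp(−age/τ) (α = 0.08 y⁻¹,
  τ = 12 y): a short-lived post-impoundment production spike that peaks
  near τ and dissipates; a mild sampling-year trend (0.004 y⁻¹); a
  per-reservoir N(0, 0.4) random intercept; multiplicative
  Gamma(shape = 20, mean 1) survey noise. `gamma_shape = Inf` switches
  the noise off exactly, enabling zero-noise identity tests.
* **Recovery bias** — recorded raw densities are true densities divided
  by 1.773056, so the pipeline's correction must round-trip exactly.
* **Dirt** — injected duplicate-dam rows, flagged natural-lake rows, and
  missing-completely-at-random areas/coordinates/discharges exercise
  every cleaning and fallback path. MCAR is the simplest mechanism that
  reaches them all; the generator makes no claim about informative
  missingness in real inventories.
* **Answer key** — `true_summary()` returns each reservoir's
  deterministic expected density at the standardization year and the
  exact total Σ density·area; `simulate_surveys()` attaches the realized
  random intercepts, the proper oracle for recovery tests.

One root seed drives per-table child streams, so enlarging the inventory
never perturbs the survey draws; identical seed and configuration give
identical output.

What the generator does *not* emulate — and what passing tests therefore
do not show about real data: the age trajectories are a parametric
stand-in (no claim about fitted shapes in real surveys), survey effort is
not spatially concentrated the way historical poisoning programs were,
real inventories' naming quirks and informative missingness are absent,
and no species composition is simulated.

## Problem sizes and tolerances

The test suite runs the parameter-recovery design at 200 reservoirs ×
5 surveys (1,000 surveys, Gamma shape 20, four balanced classes,
class means recovered within 10% and the random-intercept sd within 25%),
an end-to-end zero-noise identity at 120 reservoirs (national total
equals ground truth to 10⁻⁶ relative), a full five-schema synthetic run
at 10,000 reservoirs / ~1,500 surveys, and exhaustive k-means checks at
n = 8. IRLS/GLM agreement is asserted at 10⁻⁴, serialization and OLS
identities at 10⁻⁸ or tighter. The acceptance script's synthetic pipeline
uses 2,000 reservoirs — large enough for stable calibration statistics,
small enough to run in about a minute.

## Known limitations

* The deduplication key and natural-lake list are stand-ins for archival
  coding rules; counts on any real inventory are external benchmarks, not
  unit tests.
* Schemas 2–3 definitions are this package's own ablation choices.
* The area-approximation regression assumes one national power law; basin
  morphology varies regionally.
* The GAMM's year-term extrapolation to the standardization year is still
  an extrapolation, disciplined but not validated beyond the synthetic
  design.
* P/B conversion treats the assemblage ratio as exchangeable across
  reservoirs; latitudinal and assemblage variation in P/B is real and
  unmodelled.
* GeoJSON support covers outer polygon rings (with MultiPolygon), not
  interior holes.
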