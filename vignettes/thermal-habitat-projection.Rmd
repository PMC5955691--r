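---
title: "Projecting thermal habitat for shelf species: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Projecting thermal habitat for shelf species}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the tunable parameters and defaults,
what the synthetic world does and does not emulate, and the numerical
decisions taken where the method leaves room.

## The two-stage niche model

Trawl-survey catch data are zero-inflated: most hauls do not contain a
given species, and positive catches vary over orders of magnitude.  The
package therefore models occurrence and abundance separately
(a hurdle/delta formulation):

* **Stage 1 (occurrence).** A binomial GAM with logit link for
  presence/absence.
* **Stage 2 (biomass).** A Gaussian GAM for the natural log of biomass
  density, fitted to positive catches plus pseudoabsence rows.

Both stages use the same seven predictors — seasonal (3-month) surface
and bottom temperature means centred on the haul month, the minimum and
maximum bottom temperature and maximum surface temperature over the 12
months preceding the haul, seafloor rugosity, and sediment grain size
(Φ) — plus a categorical survey term.  The predicted biomass density is
the product `p̂ × exp(log B̂)`, always non-negative.

Assumptions worth stating plainly:

* *Depth is deliberately excluded* as a predictor, so projections can
  follow temperature into deeper water; apparent depth affinities are
  assumed to be expressions of temperature and seafloor structure.
* *The survey factor absorbs catchability.*  Between-survey gear and
  protocol differences enter as multiplicative offsets (additive on the
  log-biomass scale); they are assumed not to interact with the
  environmental terms.  Vessel-level effects are not modelled.
* *The minimum surface temperature is not a predictor* (it is nearly
  collinear with minimum bottom temperature in shelf waters).

### Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `k` | 5 | basis dimension per smooth; small by design — niche shapes are expected to be simple (unimodal-ish) and the penalty handles the rest |
| smoothing penalty | `log(n)/2` | `gamma_penalty(n)`: the complexity penalty grows with the sample count, guarding against overfitting the very large zero-expanded tables |
| `min_occurrences` | 250 | occurrence gate before fitting |
| `auc_threshold` | 0.75 | held-out discrimination gate (rank-based AUC with ties counted ½) |
| pseudoabsence density | 1e-10 | near-zero biomass anchoring the stage-2 envelope in never-occupied regions |
| pseudoabsence fraction | 0.10 | per never-observed region: `min(floor(0.10 × hauls in region), floor(0.10 × the species' observation records))`; the cap can be switched to 10% of presences (`of_presences = TRUE`) since "observations" is ambiguous in common usage |

The smooth basis is `mgcv`'s default thin-plate type; the method
specification is agnostic to spline family, and the penalty rule above
is doing the real work.  Pseudoabsence rows (log density ≈ −23.03) enter
stage 2 unweighted and are excluded from stage 1.

### Prediction at scale

Both stages are strictly additive in one-dimensional smooths, so each
term is a curve.  `predict_biomass(..., interpolate = TRUE)` evaluates
every curve once on a 1000-point grid spanning the new data and reads
values off by linear interpolation.  On century-scale projection grids
this is orders of magnitude faster than re-building spline bases per
prediction, and agrees with direct evaluation to ~10⁻⁶ relative — far
inside any ecological tolerance.  Extrapolation beyond the training
range is permitted (warm-edge expansion into newly suitable habitat
requires it); no clamp is applied by default.

## Delta-method downscaling

Climate models carry mean-state biases, so their fields are never used
directly.  For each model and scenario the package computes monthly
anomalies against that model's own 1995–2014 climatology (12 layers per
variable, so the seasonal cycle is preserved), regrids anomalies to the
observed-climatology grid by nearest great-circle cell — cells outside a
model's native domain are filled from the nearest in-domain cell, and
the filled fraction is reported — and adds them to the observed
1995–2014 climatology.  Two identities pin the construction down and are
asserted to 1e-10 in tests: anomalies average to zero over the baseline
per cell and month, and a zero-anomaly model reproduces the observed
climatology exactly.  All interannual variability in the projected
series comes from the model anomalies; the observed climatology is a
fixed mean.  Monthly (not seasonal) deltas are used because the
12-month extreme predictors need monthly resolution.

The projection grid is the fine static grid (0.05° in full-scale use)
masked to cells strictly shallower than 401 m, with rugosity and grain
size held constant through the century, and an analysis-region split at
−80.75° longitude (Gulf-of-Mexico side west of it).

## Projection and ensemble analytics

For every species × model × scenario, one summer composite per year
(July–September means; extremes over the 12 months ending in September)
drives a biomass prediction per cell, for 2007–2100.  Annual fields are
averaged into bins 2007–2020, 2021–2040, 2041–2060, 2061–2080,
2081–2100 (the first bin is the natural 14-year remainder; the rest are
the stated 20-year partition).

Centroids are biomass-weighted mean positions with weights
`density × cell area`; cell area carries the cos(latitude) convergence
factor (sphere, R = 6371 km).  Longitudes are averaged in a continuous
frame anchored past the largest circular gap between occupied
longitudes, so Aleutian-type domains straddling the antimeridian average
correctly.  Shift distance and initial bearing are spherical haversine
geodesy — the ellipsoidal correction (< 0.5%) is immaterial at this
precision — and the shift is the straight great-circle between
centroids, not an along-coast path.  Centroids may legitimately fall
over land or deep water.

Directional agreement is the mean resultant length
`R = ‖mean(unit vectors of bearings)‖`: 1 for unanimity, 0 for complete
cancellation.

## Uncertainty classification

Ensemble spread grows with the size of the shift itself, so raw
standard deviations cannot be compared across species.  Both
classifiers therefore work on the log-log mean–SD relation across all
species within a scenario:

* **DDU** regresses `ln(SD of distance)` on `ln(mean distance)` by OLS;
  the residual is the species' excess spread.  It is paired with
  directional *disagreement* `1 − R`.  A species is high uncertainty if
  either metric strictly exceeds its empirical 95th percentile, medium
  above the 75th, low otherwise.  (Classifying on `1 − R` rather than
  `R` is the orientation consistent with R = 1 meaning unanimity: high
  agreement must not be penalized.)
* **LU** fits linear quantile regressions of `ln(SD of Δlatitude)` on
  `ln|mean Δlatitude|` at τ = 0.75 and 0.95; above the 0.95 line is
  high, between the lines medium, below low.

The combined rating is high if either method says high, low only if
both say low, medium otherwise — monotone in both inputs.

### The quantile-regression solver

`rq_line()` minimizes the check loss
`Σ ρ_τ(y − a − b x)`, `ρ_τ(u) = u(τ − 1[u<0])`.  Profiling out the
intercept (whose optimum for fixed slope is a τ-quantile of the
residuals, type-1 order statistic) leaves a convex piecewise-linear
function of the slope, minimized by bracketed ternary search (240
iterations, shrinking the bracket far below machine precision).  Tests
verify the fit attains the exact optimum found by enumerating all lines
through pairs of points (an optimal solution always interpolates two
observations) at small n.

### Numerical choices

* Species with zero mean shift or zero spread have undefined logs; they
  are floored at 1 km (distance) / 0.001° (latitude) before logging.
* Percentiles use R's default linear-interpolation convention;
  exceedance is strict.  Exactly collinear inputs are a true-tie edge
  case: OLS residuals within 1e-10 of zero (relative to scale) are
  snapped to zero, and "above the quantile line" requires exceedance
  beyond 1e-9 × scale, so a degenerate ensemble rates every species
  low rather than scattering ratings on floating-point noise.
* Under these conventions, applying the classifiers to a large ensemble
  with continuous scatter reproduces the construction fractions:
  LU rates ≈ 75% low and ≈ 5% high; DDU with independent criteria
  rates ≈ 0.75² = 56% low and ≈ 1 − 0.95² = 9.75% high.  On 878
  projections those are ≈ 658 and ≈ 44 (LU) and ≈ 494 and ≈ 86 (DDU),
  which the acceptance script recomputes.

## The synthetic world

`make_world()` and its companions generate the study conditions the
pipeline assumes, with known ground truth:

* a regular angular grid with synthetic bathymetry: a coastal land
  strip, depth increasing offshore past the 401 m mask, smooth
  undulations that give rugosity structure; land and too-deep cells are
  masked, not removed, so regridding is exercised;
* monthly surface/bottom temperatures: poleward cooling
  (0.45 °C per degree latitude at the surface), an August-peaked
  seasonal cycle (4 °C surface amplitude, 1.5 °C bottom), a
  depth-dependent surface-to-bottom offset, and interannual Gaussian
  noise (SD 0.3 °C);
* a climate-model ensemble on coarser native grids (optionally trimmed
  in latitude to exercise nearest-cell fill): each model adds a constant
  bias, a scenario warming amplitude on a linear ramp that is zero-mean
  over 1995–2014 and unit-mean over 2081–2100, a latitudinal
  amplification pattern, and noise.  Default amplitudes span roughly
  0.5–1.5 °C (low scenario) and 2–4.5 °C (high), the canonical spread
  between strong mitigation and business-as-usual;
* surveys with fixed season, latitude band, haul allocation and a
  catchability multiplier; species with Gaussian thermal suitability
  `S = exp(−(SBT − T_opt)²/(2σ²))` on the 3-month seasonal bottom
  temperature, occurrence probability `min(1, prevalence × S)` (the
  simplest reading that keeps the analytic occurrence probability
  exactly checkable against simulation), and lognormal positive
  densities around `max_density × S × catchability`.

Monthly resolution suffices throughout because every downstream
quantity is a 3-month mean or 12-month extreme.  Bottom temperature is
deliberately the single dominant niche axis of the truth, so that
recovery of `T_opt` and of survey catchability ratios by the fitted
models is a meaningful test.

What the generator does **not** emulate: real coastline geometry,
currents, eddies, upwelling, spatially correlated noise, species
interactions, dispersal limits, or population dynamics.  Passing tests
therefore demonstrate that the pipeline recovers the structure it
assumes — not that real shelf ecosystems obey that structure.  In
particular, real surveys have spatially autocorrelated residuals that
the independence-based binomial tolerances here do not probe.

## Problem sizes and runtime

The package's own simulation studies are sized for a single CPU: the
demonstration pipeline uses a 10° × 5° shelf at 0.1° projection
resolution (≈ 2,900 ocean cells < 401 m), 20 species, 6,000 hauls, and
a 4-model ensemble — about two minutes end-to-end — and the
parameter-recovery study uses 10 species × 5,000 hauls.  Full-scale
use (0.05° grids, dozens of surveys, 16 models) is a straightforward
scale-up of the same calls.

## Known limitations

* Quantile regression is limited to a single covariate (all the method
  requires); no standard errors are produced for the quantile lines.
* The IDW interpolator is exact brute force (all points per target);
  for very large sediment databases a spatial index would be needed.
* Habitat projections are thermal-envelope projections: no fishing,
  productivity, carbonate chemistry, recruitment or dispersal dynamics.
  Percent-change values can explode when present-day habitat is near
  zero (warm-edge colonizers); such cases are flagged rather than
  suppressed.
* The generator's "gulf" split longitude is only meaningful for domains
  that actually span −80.75°; the demonstration world is entirely
  Atlantic-side.
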