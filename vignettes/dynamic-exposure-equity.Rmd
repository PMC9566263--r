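---
title: "Dynamic PM2.5 exposure and equity: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic PM2.5 exposure and equity: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

aerequity measures the fine-particulate (PM2.5) exposure of an urban
population whose members move: working-age residents commute, while the
elderly and young children stay near home. Assigning everyone the
concentration at their residence — the conventional static assessment —
misstates the burden whenever commuting carries people into cleaner or
dirtier air; this package quantifies that difference, and asks who bears it.
This vignette documents the models, the tunable parameters, the numerical
choices and the limits of what the built-in synthetic validation shows.

## Concentration surfaces

Hourly PM2.5 surfaces are built in four steps.

**1. Geographically weighted regression (GWR) at the monitoring stations.**
For each hour, observed station PM2.5 is regressed on five covariates —
aerosol optical depth (AOD, unitless), population density (person/km²),
NDVI (unitless, in [-1, 1]), road density (m/km²) and Euclidean distance to
the major industrial source (m) — with a spatially local fit: at each
calibration location the coefficients solve a kernel-weighted least-squares
problem, so every station carries its own intercept and slopes.

- *Kernel*: Gaussian, `w = exp(-d²/2b²)`. The bisquare kernel is available.
- *Bandwidth* `b` (m): chosen by leave-one-out cross-validation over a
  log-spaced grid (12 points between the 5% quantile of pairwise station
  distance and twice the maximum). CV is run once per week rather than per
  hour, because the station geometry does not change; the hourly surfaces
  reuse the first hour's bandwidth.
- *Conditioning*: the local normal equations are equilibrated by their column
  norms before solving, so rank diagnostics reflect collinearity rather than
  covariate units; genuinely singular local designs (locally collinear
  covariates) fall back to a small ridge (1e-8 on the equilibrated diagonal)
  with a warning and a count.

**2. Prediction onto the fishnet.** Station coefficients are transferred to
the 1000 m grid cells by inverse-distance-weighted interpolation (power 2; a
cell colocated with a station takes that station's coefficients exactly) and
the local regression equation is evaluated at each cell's covariates.
Refitting GWR at every cell is the obvious alternative; coefficient
interpolation was chosen because with ~10 stations the local fit is
identical in the station-rich interior and better behaved at the periphery,
and it is two orders of magnitude cheaper over 168 hours. Negative
predictions are clamped to zero and counted.

**3. Ordinary kriging of the fishnet predictions.** A semivariogram
(exponential by default; spherical available) is fitted to each hour's
predicted fishnet values by pair-count-weighted least squares on 12
equal-width lag bins up to half the maximum pair distance, and the ordinary
kriging system (weights constrained to sum to one by a Lagrange multiplier)
is solved per target cell. Kriging the fishnet onto itself reproduces the
inputs exactly when the fitted nugget is zero and smooths them when it is
not; the tests assert the two surfaces stay within 15% of each other on
average. Constant fields produce a degenerate pure-nugget model, flagged,
for which predictions collapse to the mean with equal weights. Duplicate
input coordinates are collapsed to their mean value.

**4. Block averaging.** The block (and community) concentration is the
area-weighted mean of intersecting cells; since blocks are cell
aggregations, the weights are the (equal) cell areas. A unit with no member
cell takes the value of the nearest cell, logged.

## Exposure under mobility

Two statistics summarise exposure.

**Exposure intensity** of a block over the week is the cumulative product of
hourly concentration and hourly population density,
`E = Σ_h conc_h × density_h` (µg·person/(m³·km²)), summed over the hours in
which concentration exceeds a threshold; `NT` counts those hours. The
threshold defaults to *none* (all hours counted). The formula is implemented
as an hourly sum — the only reading under which "cumulative time" has units
of hours and doubling every density doubles `E` (a tested linearity
property).

**Time-activity-weighted concentration** (`pod`, µg/m³) of a community is
the population-weighted mean hourly concentration its resident
origin-destination (OD) groups experience. Schedules: elderly (65+) and
children (0–6) spend every hour in the home community; the working-age group
(19–59) is at its workplace community on weekday hourly bins [8, 18) — ten
bins per day, Monday to Friday — and at home otherwise. Hour bins are
half-open. Each day is normalised by 24 hours and the week's `pod` is the
mean over days, so a uniform concentration yields `pod` equal to that
constant regardless of schedules, and `pod` is always a convex combination
of experienced hourly values (both tested). Workplaces outside the study
region fall back to the home concentration (conservative, logged);
zero-population communities are excluded and flagged. The static baseline is
the residence-only time mean, and the package reports population-weighted
regional means of both; with commuting into higher-concentration employment
centres the dynamic mean exceeds the static one — the sign property the
whole dynamic approach rests on, asserted on a constructed fixture with a
+10 µg/m³ centre.

## Walkability

The walk score is computed in three stages with a 16-point ceiling.

| stage | input | rule |
|---|---|---|
| basic | nearest facility per category | weight × (1 − distance decay) summed over categories |
| single-point | block length, intersection density | basic × (1 − combined street-form decay) |
| area | single-point per cell | population-weighted mean over the unit's cells |

Facility weights: grocery 3, restaurants 3, mall 2, café 2, bookstore, park,
entertainment venue, hospital, school, bank 1 each (total 16). Distance
decay bands are half-open [lo, hi): 0% within 500 m, 25% to 1000 m, 88% to
1500 m, 100% beyond — so a facility at exactly 500 m decays 25%. Street-form
decay adds a block-length band (0–5%) and an intersection-density band
(0–5%, per square mile as conventionally tabulated; a converter from per-km²
is provided), capping the combined decay at 10%. Only the nearest facility
per category contributes: that is the simplest rule consistent with a fixed
16-point maximum, and a per-count variant is deliberately out of scope.
Distances are straight-line; network distances can be emulated by
pre-transforming facility coordinates, but no shortest-path engine is
included. Cell population weights for the area index are the residential
(night-time) populations.

## Risk typologies

Block exposure risk is scored hourly: each hour's block exposure intensities
are split into equal-count tertiles scored 1/2/3 (168 assignments over a
week), the scores are summed per block (bounded by [168, 504]) and the sums
are tertiled again into the final low/medium/high level. The equal-count
split is stable — ties keep input order, class sizes differ by at most one,
remainders go to the lower classes — and tied values then share the lowest
class any member received, so a degenerate constant input is all-low rather
than arbitrarily split.

Walkability levels (and both community axes: weighted concentration and
age-group proportion) use Jenks natural breaks with k = 3, implemented as
the exact dynamic programme over sorted values minimising within-class sum
of squares — not a k-means heuristic — and verified against an exhaustive
search over all partitions for n ≤ 12, k ≤ 4. A constant axis degenerates
to a single class, logged. Crossing two three-level axes yields nine labels
("low-low" … "high-high"); all nine are always possible and the observed
frequency table is reported, with no silent merging of empirically absent
classes.

## Equity statistics

**Lorenz/Gini.** Communities are sorted ascending by per-capita exposure
(`pod`); the curve plots cumulative vulnerable-population share against
cumulative burden share (`pod` × population) and the Gini coefficient is one
minus twice the trapezoid area. This equals the population-weighted mean
absolute pairwise difference divided by twice the mean — asserted to 1e-9
against an independent pairwise implementation. A reading view reports the
burden share of the most-exposed 40% (the curve read from the top); it is
the same curve, not a second statistic.

**Bivariate Moran/LISA.** Spatial weights default to queen contiguity on the
unit tessellation (units are neighbours if their cells share an edge or
corner), row-standardised, with symmetric adjacency; a k-nearest-neighbour
fallback (k = 6, symmetrised by union) serves point-represented units.
Variables are z-standardised with the population standard deviation; the
global statistic is `I = Σ zx·(W zy)/n` and the local statistics
`I_i = zx_i (W zy)_i` satisfy the decomposition `I = mean(I_i)` to 1e-12.
This is the standard bivariate normalisation; the exact normalisation used
by any particular desktop GIS is not always documented, so the package
states its own. Inference permutes the second variable: full permutation for
the global statistic, conditional permutation (unit i held fixed, its
neighbours drawn from the remaining units without replacement) for the
local ones; pseudo p-values are two-sided with the +1 correction, the
z-score uses the permutation moments, and 999 permutations with a mandatory
seed is the default. Type-I error at α = 0.05 under independent variables
is verified to lie in [0.03, 0.07] over 500 replicates, and `y = x` on a
rook-weighted checkerboard reproduces the univariate I = −1 exactly. LISA
labels (HH/HL/LH/LL by Moran-scatter quadrant, `ns` otherwise) partition
the units; α = 0 silences everything.

## The synthetic city

The generator emulates the statistical structure the analysis assumes, not
any particular geography: a square monocentric region on planar projected
coordinates tiled by a 1000 m fishnet; blocks as k-means aggregations of
cells and communities as aggregations of blocks (two nested analysis
units); AOD, road density and NDVI as monocentric radial trends (pollution
and roads centre-high, greenness periphery-high) plus smooth plane-wave
fields; one major industrial source in the north-west quadrant; an
elderly-central / children-peripheral age gradient; and commuting OD flows
drawn towards central employment, which move workers at weekday working
hours and leave total population conserved hour by hour (a tested
invariant). Station observations add Gaussian noise to the latent surface.
AOD and NDVI are static within a day (AOD varies by day), population is
hourly, road density and source distance are static, matching the cadence
of the corresponding real data sources.

Two generator choices are load-bearing for validation and worth stating
plainly. First, each covariate field carries independent cell-scale texture
(i.i.d. per-cell perturbations: 0.3 on AOD, 0.08 on NDVI, 800 m/km² on road
density) on top of its smooth trends. Without it, every covariate is locally
a linear function of position, the local design is rank-deficient in effect,
and *no* estimator could recover local coefficients — with it, recovery is a
fair test, and 1 km texture is also what satellite- and map-derived rasters
genuinely look like. Second, the true coefficient surfaces vary at
wavelengths of 2.5–4× the region extent, so they are effectively smooth at
any plausible kernel bandwidth; the recovery test then measures estimation
error rather than an arbitrary smoothing-bias floor. With 200 stations and
1 µg/m³ noise the AOD slope surface is recovered with RMSE below 25% of its
amplitude and hourly fits exceed R² = 0.6 — on the default configuration the
measured ratio is about 0.15 and every one of the 168 hourly fits clears the
threshold.

Default study conditions: 20 × 20 km, 1000 m cells, 120 blocks, 40
communities, 10 stations, 168 hours (one week, Monday start), 400,000
residents, observation noise 2 µg/m³, commute fraction 0.6, elderly
proportion 25% (centre) to 10% (edge), child proportion 4% to 12%,
working-age 55%. Coefficient means put the latent surface in a realistic
40–100 µg/m³ urban range. Hourly population redistribution is deterministic
and schedule-driven; optional Poisson jitter exists but is off by default,
since no distributional detail for phone-derived counts is assumed.

What passing tests on this city do *not* show: performance under real LBS
noise and device-ownership bias, non-commuting mobility (school runs,
leisure travel), in-transit exposure along travel paths (deliberately
excluded), multi-day weather regimes, or irregular administrative
geographies with islands and enclaves. The synthetic validation establishes
that the estimators are correct and calibrated, not that any particular
city looks like the generator.

## Numerical choices and degenerate inputs

- Variogram fitting: L-BFGS-B with nugget ≥ 0, partial sill ≥ 1e-10, range
  bounded to [1e-3, 10] × the maximum lag; initial values from the first-bin
  semivariance and the sample variance. Model semivariance at zero lag is 0
  regardless of nugget, making zero-nugget kriging an exact interpolator
  (asserted to 1e-8).
- Kriging with a pure-nugget (constant-field) model short-circuits to the
  mean with equal weights rather than solving a singular system.
- Tertile and decile splits: remainders to the lowest classes; ties by
  stable input order, then tie groups take their lowest class.
- IDW coefficient transfer: exact at colocated cells via a hard match at
  distances below 1e-9 m.
- Permutation seeds: every stochastic step takes a seed derived from the
  master seed by a fixed integer map, recorded in the manifest; rerunning a
  configuration reproduces every output file checksum (tested), with the
  output directory excluded from the configuration hash so runs are
  path-invariant.

## Problem sizes

The shipped configurations are sized for interactive use: the default city
(400 cells × 168 hours, full pipeline including per-hour variogram fits and
kriging) runs in well under a minute, and the routine test suite uses an
8 km / 48 hour city. The recovery study uses 200 stations for one fitted
hour; the permutation calibration uses a 10 × 10 lattice, 999 permutations
and 500 replicates. All scale linearly in hours and roughly cubically in
stations (kriging solve).

## Known limitations

Straight-line distances throughout (no network routing); a single
industrial source; GWR bandwidth shared across hours; coefficient transfer
by IDW rather than cell-level refits (both defensible, only one
implemented); Lorenz/Gini and Moran/LISA are the only inequality and
clustering statistics (Atkinson/Theil and regionalisation are out of
scope); and a single week is the unit of analysis — longer periods require
concatenating runs.
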