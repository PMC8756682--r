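---
title: "District spatial analysis: models, conventions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{District spatial analysis: models, conventions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's account of its own methods: what each stage
computes, the conventions adopted where areal-data practice leaves genuine
choices open, and what the synthetic scenarios do and do not establish
about real district data.

## The problem

District-level health indicators — here the percentage of deliveries
attended by skilled birth personnel (SBA) and nine socio-demographic
covariates on the same percent scale — are rarely spatially independent:
neighboring districts share labor markets, health infrastructure and
culture. The workflow quantifies that dependence (global Moran's I), maps
it (LISA cluster labels), and accounts for it when estimating covariate
effects (spatial-lag and spatial-error regression compared by AIC).

## Contiguity weights

Two units are **queen** neighbors when their boundary point sets share at
least one point; the **shared-border** variant additionally requires a
common segment of positive length, excluding corner-only contact, so its
neighbor sets are always a subset of the queen sets. Contiguity is purely
topological: coordinates are treated as planar tuples and never
reprojected, since adjacency needs only shared boundary points.

Numerical choices:

* **Snap tolerance.** Vertices are snapped to a grid of pitch
  `snap_tolerance` (default `1e-7` coordinate units) before intersection
  tests, because real boundary files routinely carry sub-micron vertex
  mismatch between adjacent polygons. Contact detection then accepts a
  vertex of one polygon lying on an *edge* of the other (a T-junction), not
  only vertex-on-vertex coincidence.
* **Islands.** Units with no neighbors (real archipelago districts, for
  instance) are kept, recorded in `$islands`, given an all-zero row after
  row standardization, excluded from LISA classification (label
  `"island"`), and block the global statistics only when *all* units are
  islands.
* **Row standardization.** Analysis defaults to row-standardized weights,
  the convention of the standard GeoDA-style workflow, so the spatial lag
  is a neighbor mean; the Moran formulas divide by `S0` and are therefore
  valid for binary weights too, and both styles are exercised in the tests.

## Global and bivariate Moran's I

The univariate statistic is the classical double sum
`I = (n/S0) Σ_ij w_ij (x_i − x̄)(x_j − x̄) / Σ_i (x_i − x̄)²`, with
expectation `−1/(n−1)` under random permutation of values across units.

The bivariate statistic crosses variables: both are **z-scored with the
population (1/n) variance** and
`I_xy = (n/S0) Σ_ij w_ij z_x,i z_y,j / Σ_i z_y,i²`. The population
convention is deliberate: it makes `I_xy` with `y = x` collapse *exactly*
onto the univariate statistic, and makes the local statistics below sum
exactly to `S0 · I` on both the univariate and bivariate paths. These two
identities are enforced to `1e-12`/`1e-10` in the test suite.

## Permutation inference

The reported significance is a **pseudo p-value** from random
reassignment: `p = (m+1)/(R+1)` with `R = 999` permutations by default, so
the smallest attainable p is `0.001`. Univariate nulls permute the variable
itself; bivariate nulls permute `y` against fixed `x`; the local
(conditional) version holds each unit's own value fixed and redraws its
neighbors' values from the remaining `n−1` units, independently per unit.

**Extremity convention.** `m` counts null statistics at least as extreme as
the observed one, where extremity is measured as absolute deviation from
the permutation-null mean. A directional count toward the observed sign
(the GeoDA convention) was considered and rejected: because the direction
is chosen after seeing the data, its rejection rate under spatial
randomness is about twice the nominal level (analytically ≈ 0.10 at
α = 0.05; measured 0.095–0.104 on 10×10 lattices), which would make the
mapped cluster counts systematically anti-conservative. The symmetric count
has exact size α, still attains the `1/(R+1)` floor for strongly clustered
data, and still flags negative statistics — required both for spatial
outliers in LISA maps and for negative bivariate associations. Calibration
is verified empirically in the suite (global: 200 datasets; local: 100
datasets).

No multiple-testing correction is applied to the per-unit LISA p-values,
matching standard practice for exploratory cluster maps; the hotspot count
is therefore a descriptive, not an inferential, quantity.

## LISA classification

Each non-island unit gets a Moran-scatterplot quadrant from the signs of
its standardized value and standardized neighbor lag: `(+,+)` high-high,
`(−,−)` low-low, `(+,−)` high-low, `(−,+)` low-high — so the high/low
thresholds sit at the variable means. A value exactly at the mean is
tie-broken to the "low" side (a documented convention; it affects only
measure-zero inputs). Significant units become `hotspot`, `coldspot`,
`high_low_outlier` or `low_high_outlier`; the rest are `not_significant`.
Labels are invariant to positive affine rescaling of the variable, and
raising α can only grow the significant set (both tested).

## Spatial regression

All three models are estimated with Gaussian likelihoods, reported with
`AIC = 2k − 2 logL`:

* **OLS** via `stats::lm`, log-likelihood at the ML variance (`RSS/n`), so
  its AIC is directly comparable with the spatial fits. `k` = coefficients
  (incl. intercept) + 1 for the variance.
* **SLM / SEM** by maximising the log-likelihood concentrated in the
  scalar spatial parameter. At each candidate value the coefficients and
  variance are profiled out by least squares (SLM: regress `y − δWy` on X
  via the two-regression decomposition; SEM: regress the spatially
  filtered `(I − λW)y` on `(I − λW)X`), and the Jacobian `log|I − ρW|` is
  added as `Σ log(1 − ρ λ_i)` from a one-time dense eigenvalue
  decomposition of W (the design envelope is a few thousand units; 640 is
  the reference scale, and sparse-Cholesky log-determinants are out of
  scope). `k` adds one more parameter for δ/λ.

Numerical conventions:

* The search interval is the admissible `(1/λ_min + 1e-5, 1/λ_max − 1e-5)`
  (for row-standardized W, `λ_max = 1`); the bounded scalar optimizer runs
  at tolerance `1e-8` and an optimum at the interval edge raises a
  non-convergence error rather than returning a boundary value.
* Row-standardized W is asymmetric but similar to a symmetric matrix, so
  its eigenvalues are real; if a weight matrix ever yields complex
  eigenvalues beyond `1e-8`, the real parts are used with a warning.
* At δ = 0 (resp. λ = 0) the concentrated likelihood equals the OLS
  log-likelihood to `1e-9` — the tested guarantee that spatial fits can
  never be worse than their own null point.
* Standard errors come from the numerically differentiated observed
  information of the full likelihood at the optimum (step `1e-6`), with
  normal-theory p-values.
* "R²" is the adjusted R² for OLS; for ML spatial models a true adjusted
  R² is undefined, so a clearly-labelled **pseudo R²** (squared Pearson
  correlation of fitted and observed values) is reported, with fitted
  values including the estimated spatial component (`δWy + Xβ` for SLM;
  `Xβ + λW(y − Xβ)` for SEM).
* Model ranking: ascending AIC; ties broken by higher R² measure, then by
  simplicity (OLS before SLM before SEM).

## The synthetic scenarios

Real district-level survey aggregates of this kind are access-restricted,
so the generator emulates their *structure*, not their numbers: a 32×20
lattice of 640 square districts (640 factors cleanly; the lattice is a
convenience, not geography), nine percentage covariates with plausible
means and spreads drawn as simultaneous-autoregressive fields
(`(I − ρW)^{-1}ε`, ρ = 0.85) and affinely rescaled to the percent scale —
which puts their global Moran's I in the 0.4–0.75 regime typical of
district indicators — and an outcome generated under a spatial-error
process with λ = 0.7, innovation σ = 5 percentage points, and coefficient
signs following the reference pattern for these covariates (positive mass
media, antenatal care, first birth order, female headship, rural; negative
non-Hindu). The intercept centres coverage near 81%. Every generating
parameter is recorded in `$truth`, and regeneration under the same seed is
bit-identical.

What the generator does **not** emulate: survey design effects (weighting,
clustering, stratification of the underlying microdata), the irregular
adjacency graph of real districts, denominator-driven heteroskedasticity
(small districts estimated from few births), non-Gaussian noise, and
cross-covariate correlation (fields are drawn independently). Passing
recovery tests therefore show the estimators are correct under their own
assumptions at realistic size and signal — not that those assumptions hold
for any particular survey. One known edge: the outcome is clamped to
[0, 100] for storage as a percentage, which slightly censors ~the top few
percent of units in the study-scale scenario; parameter-recovery tests use
the unclamped simulators directly.

## Problem sizes and determinism

The test suite exercises: exact hand cases on 2×2 and 3×3 grids; naive
double-loop oracle equivalence on 20 random lattices up to n = 49;
permutation calibration on 10×10 lattices (200 datasets global, 100 local,
R = 999); parameter recovery with 50 replicates on 20×20 lattices
(δ = 0.5, λ = 0.7, β = (1, 2), σ = 1); and the full 640-unit pipeline run
twice to verify byte-identical outputs. Every random draw is seeded; the
pipeline derives per-stage seeds from one master seed by stage-name
hashing, so stages are individually reproducible.

## Known limitations

* Queen contiguity detects boundary *contact*, not topological overlap
  repair; invalid self-intersecting polygons are out of scope.
* Higher-order, distance-band, k-nearest and kernel weights are not
  implemented (queen and shared-border cover the intended workflow).
* No Lagrange-multiplier specification tests, spatial Durbin/SARAR
  models, heteroskedasticity-robust inference, or survey-weighted
  regression.
* The dense eigenvalue log-determinant limits the regression stage to a
  few thousand units.
* Shapefile support covers polygon records (type 5) with a string id
  column — sufficient for boundary files of areal units, not a general
  GIS reader.
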