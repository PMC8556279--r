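---
title: "Methods: spatial panel models, GTWR, and mortality attribution in roadpm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial panel models, GTWR, and mortality attribution in roadpm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(roadpm)
```

`roadpm` estimates how strongly county-level annual mean PM2.5 responds to
on-road transportation, measured as CO2 emission density (10^6 t per km^2),
and converts the estimated response into contribution shares, vehicle-mileage
equivalents, and PM2.5-attributable premature deaths. This vignette is the
package's account of the statistical machinery: the models and their
assumptions, the tunable parameters, what the synthetic data generator does
and does not emulate, the numerical choices, and known limits.

## 1. Spatial weights

Counties are treated as polygons; two are neighbours under the *Queen*
criterion when their boundaries share at least one point, so on a regular
lattice each interior cell has eight neighbours. Contiguity is computed from
closed-rectangle overlap with a snap tolerance of 1e-9 of the cell size,
which absorbs floating-point boundary coordinates in polygons read from
GeoJSON. Row standardization turns the binary links into equal shares
1/|N(i)|, so the spatial lag of a variable is the neighbourhood mean.
Isolated units are allowed (real county maps contain islands); their lag is
zero and their weight row stays empty. Neighbours are stored in ascending id
order so that serialized weights are reproducible byte for byte.

A row-standardized symmetric contiguity matrix is similar to a symmetric
matrix, hence has real eigenvalues with maximum 1; the package computes the
full spectrum once per fit and uses it both for the stationarity interval of
the spatial parameters and for the log-determinants in the likelihood.

## 2. Panel models

All panel estimators work on the *within transformation*: outcome and
regressors demeaned within each county, which removes time-invariant county
effects exactly. The fixed-effects model is then ordinary least squares with
degrees of freedom `NT - N - K`; fixed effects are recovered as county means
of the partial residuals, and the reported R-squared is the within
R-squared.

The spatial variants add a spatially lagged outcome (coefficient `lambda`),
a spatially autocorrelated error (coefficient `rho`), or both. Estimation is
Gaussian maximum likelihood concentrated over the spatial parameters: given
`(lambda, rho)` the slope vector is least squares on the doubly filtered
data `B(Ay)` on `BX` with `A = I - lambda W`, `B = I - rho W` applied year
by year, and the log-determinants `T_eff log|A| + T_eff log|B|` come from
the precomputed eigenvalues. Because demeaning consumes one period per
county, the demeaned likelihood uses `T_eff = T - 1` effective periods; this
is what makes the error-variance estimate consistent and, in simulation, the
spatial parameters mean-unbiased at the scale the tests use. Spatial
parameters are constrained to the interval given by the extreme eigenvalues
of `W`; hitting the boundary raises a convergence warning rather than a
silent clip.

Numerical choices: the two-parameter profile is optimized by L-BFGS-B
restarted from `(0, 0)` and the four `(±0.5, ±0.5)` corners, keeping the
best likelihood with ties broken by the smaller `|lambda| + |rho|`;
convergence tolerance is 1e-8 on the log-likelihood; one-parameter variants
use golden-section search. Rank-deficient designs abort with the names of
the collinear columns rather than a generic error.

**Impacts.** With a spatially lagged outcome, a regressor change propagates
through the multiplier `(I - lambda W)^{-1}`, expanded as the truncated
series `sum_{s=0}^{500} lambda^s W^s`. For each regressor the *direct*
impact is the mean diagonal of the accumulated matrix times the coefficient,
the *total* impact the mean row sum times the coefficient, and the
*indirect* (spillover) impact their difference — an exact identity by
construction. For row-standardized weights the total converges to
`beta / (1 - lambda)`; at 500 terms the truncation error is below 1e-8 for
`|lambda| <= 0.8`, which the tests verify against a dense matrix inverse.
Standard errors for impacts are not computed: the package reports
confidence intervals for coefficients only, and point impacts.

**Model selection battery.** The battery mirrors standard panel practice:
F test for individual effects (pooled vs within), Breusch–Pagan LM (pooled
vs random effects), Hausman with a Swamy–Arora random-effects side, and the
locally robust LM lag/error pair computed on the pooled within-transformed
data. Two degrees-of-freedom details matter under demeaning and were fixed
by theory and then confirmed by null simulations: the error variance uses
denominator `N(T-1)` and the kernel trace scales as `(T-1) tr(W'W + WW)`.
With them, both robust tests hold 5 % size to within simulation error. A
caveat worth recording: the "local robustness" of the pair protects size
against *small* amounts of the other alternative; under a strong
misspecification (say a lag of 0.7) both tests reject essentially always.
The decision tree follows the usual reading at the 0.1 % level: significant
F, BP-LM and Hausman select fixed effects; significant robust LM lag and/or
error then upgrade to the lag, error, or combined model.

## 3. GTWR

The geographically and temporally weighted regression fits one weighted
least-squares regression per observation over its `k` nearest space-time
neighbours (the observation itself included), with Gaussian weights
`exp(-d^2/b^2)` and the adaptive radius `b` equal to the k-th smallest
combined distance, so the k-th neighbour itself receives weight `exp(-1)`.
The combined squared distance is `phi_S dS^2 + phi_T dT^2` with `dS` planar
Euclidean in km and `dT` in years.

Two structural decisions:

* **Only the ratio matters.** Under an adaptive bandwidth, jointly rescaling
  `(phi_S, phi_T)` rescales all distances and the radius alike and leaves
  every weight unchanged (a property the tests assert numerically). The
  package therefore fixes `phi_S = 1` and searches `tau = phi_T / phi_S`
  jointly with `k`.
* **Local fits pool space and time.** Each subsample is a set of space-time
  neighbours, not a cross-section; no fixed effects enter the local fits —
  the local intercept absorbs them.

Bandwidth selection is leave-one-out cross-validation over a user-supplied
grid of `(k, tau)`: each observation is predicted from a local fit that
excludes only the focal observation (not its county's other years — the
simplest reading of minimizing the sum of squared prediction errors), and
ties go to the smaller `k`, then the smaller `tau`. Singular local designs
fall back to a ridge jitter of 1e-8 times the trace of the local
cross-product, with a fallback counter reported on the fit. A `fixed_b`
option replaces the adaptive radius, and a very large `fixed_b` flattens the
kernel so every local fit reproduces pooled OLS — the limit the tests check
to 1e-6. A `year_range` argument restricts the panel before selection and
fitting, the practical remedy when the full space-time weight structure of
the earliest years is not wanted; restriction is first-class in both the
GTWR functions and the pipeline configuration.

## 4. Attribution

The local CO2 coefficient `beta_it` (µg/m^3 per 10^6 t/km^2), the CO2
density and the PM2.5 level combine into the contribution share
`Con_it = beta_it CO2_it / AP_it × 100`. Shares can leave [0, 100] because
of the other covariates and residual noise; the clamp sets negatives to 0
and values above 100 to 100, idempotently, and is always applied before
mortality attribution — it is what guarantees `MAPOR <= MAP`. A
`co2_averaging` switch chooses between the year-specific CO2 density
(default, matching the year-indexed definition) and the county's
study-period mean.

Mortality propagation starts from an anchor-year baseline and applies
`MAP_t = MAP_{t-1} (1 + CPD (AP_t - AP_{t-1}))` forward and its exact
algebraic inverse backward, so a forward-backward round trip returns the
anchor to machine precision (asserted to 1e-9). The concentration-mortality
coefficient `CPD` defaults to 0.012 per µg/m^3, the midpoint of the 0.7-1.6 %
per µg/m^3 range reported for all-cause annual mortality; it is a plain
argument. Propagation runs county by county; yearly national totals are sums
of county values. Deaths are kept as reals throughout and rounded only in
display-oriented CSV output, which avoids the off-by-one inconsistencies that
integer-rounded tables produce. The attribution percentage is the pooled
ratio `sum(MAPOR) / sum(MAP) × 100`, *not* the mean of yearly percentages;
the tests pin the distinction on a crafted two-year example.

Vehicle-mileage equivalents use 404 g CO2 per mile and 1.61 km per mile, so
one million tons of CO2 corresponds to `1e12 / 404 × 1.61 ≈ 3.985e9`
vehicle-km. The factor is always computed exactly from the constants and
rounded only for display (3.99 at three significant figures); dividing it by
a positive total-impact coefficient gives billion vehicle-km per km^2 per
µg/m^3.

## 5. The synthetic data generator

The generator is first-class, tested code: it defines the conditions under
which every estimator in the package is exercised.

**Geometry.** Rectangular lattices of congruent square cells (default in the
pipeline: 10 × 10 cells of 50 km, a county-sized grid), with centroids and
cell bounds in planar km. This deliberately does *not* emulate the irregular
polygons, area heterogeneity, coastlines or islands of a real county map;
Queen contiguity on a lattice is plain Moore adjacency, which is exactly why
it is easy to verify against a brute-force oracle.

**Constant-coefficient mode** draws the outcome from the combined
lag-error process itself, solving `y_t = (I - lambda W)^{-1}(X_t beta +
alpha + (I - rho W)^{-1} nu_t)` exactly each year — so estimator recovery
tests target the exact model being fitted. Defaults: `lambda = 0.4`,
`rho = 0.3`, Gaussian noise `sigma_nu = 0.5` µg/m^3, Gaussian county effects
with `sigma_alpha = 0.5` around a base level, plus a loading
(`gamma_alpha = 0.5`) of the county effect on urbanization (the z-score of
county-mean log CO2 density). That loading makes the unobserved county
effect correlated with the regressors — the situation that requires fixed
effects and gives the Hausman test something to detect. Covariates mimic the
applied setting in type and unit: lognormal CO2 density (median 0.04, log-sd
1.2, in 10^6 t/km^2, so urban cells carry most of the information), a
land-cover composition drawn per county and anchored at the first and last
year with linear interpolation between (the standard treatment for sparse
land-cover vintages, and a live test of the interpolation routine),
lognormal population density, and temperatures/humidities whose yearly
anomalies contain a shared national shock plus smooth spatial gradients.
The spatially structured anomalies matter: they give the within-transformed
regressors the cross-sectional structure that separates `lambda` from `rho`
in the likelihood, and they put the within R-squared of the fixed-effects
fit in the 0.35-0.45 range, the order observed in county panels of this
kind. True slopes default to field-plausible magnitudes (0.646 for CO2
density; a few hundredths per percentage point of developed land; 0.2 per
summer-K).

**Varying-coefficient mode** generates
`y = beta_0(x,y,t) + sum_k beta_k(x,y,t) x_k + nu` from smooth trigonometric
surfaces: half-period sinusoids across the lattice and a half-cosine over
the year range (defaults: slope surfaces 0.30 ± 0.25 and 0.20 ± 0.20
spatially, ± 0.10 temporally for CO2; intercept 10 ± 0.5). The slope
surfaces attach to *standardized* covariates (z-scores of log CO2 and log
population density). Two design points deserve justification. First,
standardization: local-coefficient recovery is only informative when the
regressor carries comparable variance everywhere; raw CO2 density is
right-skewed over orders of magnitude, so rural neighbourhoods would have
essentially no within-subsample contrast and recovery would measure
covariate scaling, not estimator quality. Second, surface amplitudes: an
intercept surface much larger than the slope surfaces is locally confounded
with the slopes when covariates vary mostly across counties, capping
recovery even without noise; the default keeps the intercept amplitude at
the scale of the slope amplitudes. The reference noise level for
varying-mode experiments is `sigma_nu = 0.25`, which puts the global GTWR
R-squared near 0.8 — the regime in which a local model is clearly preferable
to the global one. Under these conditions the correlation between true and
estimated CO2-coefficient surfaces exceeds 0.8 at 400 observations, which
the acceptance suite asserts.

**Mortality baseline.** Anchor-year deaths are Poisson draws with county
means proportional to population density, scaled to an expected national
total of 54,730 — the scale of published national estimates of
PM2.5-attributable premature deaths — so integer counts arise naturally and
the propagation recursion then produces reals.

**What passing tests do and do not show.** The generator matches the
estimators' assumptions by construction. Passing recovery tests therefore
demonstrates correctness of the implementations, not robustness to the ways
real data violate those assumptions: irregular geometry, non-Gaussian and
heteroskedastic errors, measurement error in the downscaled concentrations,
emission inventories with their own spatial error structure, or confounding
by unmodelled industrial sources. Results on real panels inherit all of
those caveats.

## 6. Problem sizes and runtime

The test and acceptance problem sizes are chosen as the smallest
configurations at which each property is sharp: estimator recovery on a
15 × 15 lattice over 8 years (30 replications, mean estimates within 0.05 of
truth), robust-LM size and power at n = 100, T = 5 (500 replications each),
GTWR surface recovery at 400 observations with a 3 × 3 cross-validation
grid, impact-series verification on a 4 × 4 lattice against a dense inverse,
and a 10 × 10 × 14-year end-to-end pipeline. The full test suite and the
acceptance script each run in well under a minute on a single CPU.

## 7. Known limitations

* The combined lag-error likelihood uses dense eigendecomposition of `W`;
  this is exact and fast to a few thousand counties but not designed for
  much larger maps.
* No standard errors on impacts, no random-effects *spatial* models, no GMM
  or dynamic panels.
* The Durbin-type specification is implemented in its combined lag-error
  form; spatially lagged regressors (WX terms) are not included by default.
* GTWR prediction intervals and hat-matrix diagnostics (effective degrees of
  freedom, AICc bandwidth selection) are not provided; selection is
  cross-validation only.
* Attribution propagates a single deterministic CPD; uncertainty in the
  concentration-mortality relationship is not carried through the death
  estimates.
* Geographic (lon/lat) inputs are not auto-projected; coordinates are
  expected in planar km.
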