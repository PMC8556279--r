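# roadpm

Spatial panel and geographically-temporally weighted attribution of
county-level PM2.5 to on-road transportation.

## The problem

On-road vehicles emit CO2 in near-fixed proportion to fuel burned, so a
county's annual on-road CO2 emission density (10^6 t per km^2) is a clean
proxy for vehicle usage. County-level annual mean PM2.5 (µg/m^3) responds to
that usage, to land cover, population density and weather — and to pollution
drifting in from neighbouring counties. `roadpm` implements the estimation
chain that turns a balanced county-year panel of these quantities into:

1. a global marginal effect of on-road CO2 density on PM2.5, from spatial
   panel models that account for cross-county spillovers;
2. local, county-year-specific effects from a geographically and temporally
   weighted regression (GTWR);
3. per-county contribution shares of on-road transportation to PM2.5,
   vehicle-mileage equivalents, and PM2.5-attributable premature deaths.

Every stage is testable without external data: a synthetic-data module
generates lattice "county maps" under the exact processes the estimators
assume.

## Models

With `i` indexing counties, `t` years, `W` the row-standardized Queen
contiguity matrix and `AP` the PM2.5 concentration:

* **FEM (within estimator)** — `AP_it = β'X_it + α_i + µ_it`
* **Spatial lag (SPAM)** — `AP_it = λ W_i AP_t + β'X_it + α_i + µ_it`
* **Spatial error (SPEM)** — `AP_it = β'X_it + α_i + ε_it`, `ε_it = ρ W_i ε_t + ν_it`
* **Combined lag–error (SPDM form)** — both λ and ρ, fitted by concentrated
  maximum likelihood on the demeaned panel; coefficients decompose into
  direct, indirect (spillover) and total impacts via the truncated series
  `Σ_{s=0}^{500} λ^s W^s`.
* **GTWR** — one weighted least-squares fit per observation,
  `β_it = (X'W_it X)^{-1} X'W_it y`, Gaussian kernel `exp(−d²/b²)` over the
  `k` nearest space-time neighbours, combined distance
  `d² = φ_S dS² + φ_T dT²`, with `(k, τ = φ_T/φ_S)` chosen by leave-one-out
  cross-validation.

Model choice follows the classical battery (F test for individual effects,
Breusch–Pagan LM, Hausman, locally robust LM lag/error tests). The
attribution stage computes the contribution share
`Con_it = β_it · CO2_it / AP_it · 100`, clamps it to [0, 100] %, propagates
an anchor-year mortality baseline with
`MAP_it = MAP_it−1 · [1 + CPD · (AP_it − AP_it−1)]` (CPD = 0.012 per µg/m^3),
and forms `MAPOR_it = MAP_it · C_it` and the attribution percentage
`PTA = Σ MAPOR / Σ MAP · 100`.

## Worked example

```r
library(roadpm)

# 1. verify the estimator on a known truth: 15x15 lattice, 8 years,
#    true lambda = 0.4, rho = 0.3, beta = (1, -2)
geom <- make_lattice(15, 15, cell_km = 50)
w    <- row_standardize(queen_weights(geom))
pan  <- simulate_panel(geom, 2001:2008,
                       dgp_params(beta = c(x1 = 1, x2 = -2), lambda = 0.4,
                                  rho = 0.3, sigma_nu = 1, sigma_alpha = 1,
                                  gamma_alpha = 0, base_level = 25,
                                  covariates = iid2, seed = 1), w)  # iid2: two N(0,1) columns
sac <- fit_spatial_panel(pan, w, model_spec(regressors = c("x1", "x2")), "sac")
panel_impacts(sac, w)
```

```
Spatial panel model (sac): 225 counties x 8 years
  lambda (spatial lag)   =   0.3657
  rho    (spatial error) =   0.2882
  log-likelihood = -2213.119, R2 = 0.867
   estimate std_error
x1  0.98572    0.0234
x2 -2.00972    0.0232
  term direct indirect  total
1   x1  1.009    0.546  1.554
2   x2 -2.056   -1.112 -3.168
```

The spatial parameters and slopes land on the truth; for `x1` the total
impact 1.554 ≈ 1/(1 − λ̂) times the coefficient, i.e. roughly a third of the
effect of a regressor change arrives through neighbouring counties.

```r
# 2. the applied chain on a synthetic county panel (10x10, 2003-2016)
panel <- simulate_panel(make_lattice(10, 10, 50), 2003:2016,
                        dgp_params(seed = 1), w2)
panel_diagnostics(panel, model_spec())
robust_lm_tests(fit_fem(panel, model_spec()), w2)
```

```
Panel specification tests:
  F (individual effects) stat =     18.354  p = 4.562e-183
  Breusch-Pagan LM       stat =   2327.761  p = 0
  Hausman                stat =     77.785  p = 3.949e-12
Panel specification tests:
  robust LM lag          stat =     22.107  p = 2.579e-06
  robust LM error        stat =     39.565  p = 3.174e-10
```

All five tests reject at the 0.1 % level, so the decision tree recommends
the combined lag–error model. GTWR and attribution follow:

```r
bw   <- select_bandwidth(panel, model_spec(), k_candidates = c(40, 80, 160),
                         tau_candidates = c(100, 2500))
gfit <- fit_gtwr(panel, model_spec(), bw)
mileage_per_unit_pm25(0.646)            # Gkm/km2 per ug/m3 for a typical coefficient

baseline <- simulate_baseline_mortality(panel, 2010, total_deaths = 54730, seed = 2)
mort   <- propagate_mortality(baseline, panel, cpd = 0.012)
surf   <- clamp_contribution(contribution(gfit, panel))
attributable_deaths(mort, surf)
```

```
GTWR fit: 1400 observations, k = 80, tau = 100, global R2 = 0.930
0.646 ug/m3 per Mt/km2  ->  6.17 Gkm/km2 per ug/m3 (CI 5.70-6.72)
Attribution over 1400 county-years (14 years): pooled PTA = 0.19%
 year map_total mapor_total pta_pct
 2003     55103         113    0.20
 2004     55112          98    0.18
 ...
 2016     55000          92    0.17
```

A coefficient of 0.646 µg/m^3 per 10^6 t/km^2 converts to about 6.17 billion
vehicle-km per km^2 for each 1 µg/m^3 of PM2.5 (404 g CO2 per mile, 1.61 km
per mile). On this synthetic map, on-road transportation accounts for about
0.2 % of PM2.5-attributable deaths; the share is a property of the simulated
emission levels, not a real-world estimate.

A single-command version of the whole chain, with a reproducibility manifest
(config echo, seed, per-stage timings, MD5 hashes of every output):

```r
run_pipeline(default_config(seed = 1, out_dir = "run1"))
```

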