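---
title: "Methods: meta-analysis of stomatal conductance responses to global change"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: meta-analysis of stomatal conductance responses to global change}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gsmeta)
library(dplyr)
```

## The problem and the data

Stomata regulate the exchange of water vapour and CO2 at the leaf surface,
so shifts in stomatal conductance (g_s, mol H2O m⁻² s⁻¹) under global
change propagate to transpiration, photosynthesis, and land-surface water
budgets. Manipulation experiments impose a single factor — elevated CO2
(eCO2), warming (eT), increased or decreased precipitation (iP/dP),
nitrogen addition (eN), elevated ozone (eO3) — or a two-factor combination,
and report control and treatment g_s means with standard errors and
replicate counts. `gsmeta` pools such paired observations.

A valid observation needs positive means in both arms (the log ratio must
exist), at least three replicates per arm, non-negative standard errors,
and a positive treatment magnitude. `read_observations()` enforces these as
row-level rejections with named reasons rather than failures, because
compiled literature tables routinely contain a few malformed rows and an
analyst needs the audit trail, not a crash. Tables that report standard
deviations instead of standard errors are converted via `SD/sqrt(n)`
(`dispersion = "sd"`). Column naming is configurable through a YAML schema
map because compiled datasets rarely share a header convention. Rows
missing climate covariates are kept for pooling and only drop out of the
moderator regressions that need them.

## Effect sizes and the random-effects model

The effect size is the log response ratio `lnRR = ln(mean_T / mean_C)`
with within-study variance `SE_T²/mean_T² + SE_C²/mean_C²`. The
random-effects model adds a between-study variance τ² to every
observation's variance before weighting — `v = v_within + τ²`, `w = 1/v`.
τ² is estimated by restricted maximum likelihood with Fisher scoring
(tolerance 1e-8 on successive values, at most 100 iterations, started from
the DerSimonian–Laird moment estimate, with DL as the documented fallback
if scoring fails to converge). Both estimators accept a moderator design
matrix, in which case τ² is residual heterogeneity. The test suite
cross-checks both estimators against `metafor`.

Two orderings matter and are fixed deliberately:

* τ² is estimated on the raw effects first; weights and the adjusted
  weights are computed afterwards from `v_within + τ²`. The variance
  definition precedes the weight definition.
* For sensitivities, τ² is estimated on the *sensitivity* scale
  (`lnSens = lnRR/Δ`, `v_sens = v_within/Δ²`). Observations within one
  sensitivity analysis carry different Δ, so a single τ² cannot live on the
  lnRR scale and divide consistently; heterogeneity is a property of the
  scale being pooled.

Observations of the same species at the same site (within one factor set)
are non-independent: each raw weight is divided by the size of its
(site, species, factor set) group, `w* = w/n_ob`, so each species-site unit
contributes one unit of total weight. Single- and combined-factor
observations of one species never share a group because they enter
different analyses. The pooled mean, its standard error `sqrt(1/Σw*)`, the
95% interval `±1.96·SE`, a two-sided normal p-value, and the
back-transformed percentage `(exp(x)−1)·100` follow. The normal (not t)
interval is intentional: the interval definition hard-codes 1.96, and the
z-test keeps pooling and subgroup tests on one convention.

If both reported SEs round to zero and τ² is also zero, the weight would be
infinite; raw weights are capped (default 1e8, `max_weight`) so a single
rounded row cannot absorb an entire analysis.

### Standardized sensitivities

Treatment magnitudes are standardized before division: 100 ppm CO2, 1 °C,
10 % precipitation change, 1 g N m⁻² yr⁻¹, 10 ppb O3 per unit. Decreased
precipitation keeps a positive Δ — direction is carried by the factor code
`dP` — so a negative pooled sensitivity reads "% change per 10 %
precipitation decrease" and the division never flips sign. Magnitudes are
inputs, so the same machinery pools responses (`metric = "rr"`) and
sensitivities (`metric = "sens"`).

## Subgroups and moderators

`pool(..., by =)` runs the mixed-effects subgroup convention: one common τ²
estimated with group membership as a moderator (a per-group τ² is available
via `tau2_scope = "within"`), per-group pooled estimates with adjusted
weights, and the between-group statistic
`Q_B = Σ_g W_g (θ̂_g − θ̂)²` with `W_g = Σ w*` in group and θ̂ the overall
weighted mean, referred to χ² on `groups − 1` degrees of freedom. Biome and
climate analyses in `run_pipeline()` use outdoor experiments only — indoor
plants grow in controlled environments and carry no site-climate signal —
while the indoor/outdoor comparison itself is a subgroup analysis on the
setting label.

Meta-regression is weighted least squares on the ln scale with weights
`w*`, the residual τ² of the moderator model folded in by REML.
Coefficient covariance is the inverse-variance form `(XᵀWX)⁻¹`, the
moderator test a Wald χ² on all non-intercept terms, and
`R² = max(0, 1 − τ²_model/τ²_null)` — the proportional reduction in
heterogeneity, clamped because a worse-than-null fit is reported as zero,
not negative. The nonlinear form is a restricted cubic spline (natural
cubic, linear beyond the outer knots, Harrell parameterisation built
in-package) with 4 knots at the weighted 5/35/65/95 percentiles — the
family's conventional default; knot placement for any particular published
curve is unknowable, so curve-for-curve reproduction is out of scope.
`form = "auto"` fits both and keeps the higher-R² fit, ties to linear for
parsimony, and falls back to linear with a warning when the spline fit
fails. "Ambient g_s" as a moderator is the control-arm mean of the same
observation — the only ambient measurement a paired record carries.

## Two-factor interactions

`build_triples()` matches each combined-factor observation to its two
single-factor arms within the same study, site, and species; replicate
observations of an arm are collapsed by inverse-variance averaging first,
and incomplete factorials are logged and skipped. The additivity contrast
is `d = lnRR_ab − (lnRR_a + lnRR_b)` with `v_d = v_ab + v_a + v_b`. The
shared control group makes the arms positively correlated, which this
independence approximation ignores; v_d is therefore slightly conservative
(biased upward), pushing borderline calls toward "additive". No covariance
correction is attempted because the paired design does not report the
cross-arm covariances.

Classification uses a z-test on d rather than raw geometry — in finite
samples every point is off the 1:1 line, so "on the line" must mean "within
sampling error". A significant d is synergistic when it pushes the combined
effect further in the sum's direction (above the line for positive sums,
below for negative sums) and antagonistic when it pulls back toward zero;
when the sum itself is indistinguishable from zero its direction is
undefined and the call is "indeterminate". The trend of combined on summed
effects is a weighted regression (weights `1/v_d`, toggleable); slope 1
with intercept 0 is additivity, slope < 1 attenuation. Because both axes
are measured with error, this regression attenuates toward zero when
measurement noise is large relative to the spread of true effects;
recovery simulations therefore use well-replicated arms (small
`se_cv`, larger n) so the attenuation term is negligible — the estimator
is a diagnostic of the additive pattern, not an errors-in-variables
corrected slope.

## Publication bias

`egger_test()` is the classic Egger regression: the standardized effect
`y/√v` on precision `1/√v` by OLS, t-test of the intercept on k−2 degrees
of freedom. A location shift of all effects moves the slope, not the
intercept test — a property the suite asserts. The test runs per factor
set; within-study variances (not τ²-inflated ones) are used, matching the
classic formulation.

## Projection

Biome-level projection multiplies a pooled sensitivity by a scenario's
forcing in standardized units: `ln prediction = lnSens̄ × Δ`, interval
bounds multiplied bound-wise, then back-transformed. The forcing is
treated as known — the sensitivity is the only uncertain term — because
propagating scenario uncertainty would require forcing ensembles that are
deliberately outside this package (forcings arrive as user-supplied
scalars, not rasters). Cells whose sensitivity interval spans zero are
flagged insignificant; biome-factor cells without a pooled sensitivity are
returned as `no_data`. A guard warns when Δ exceeds the largest
standardized magnitude observed in the experiments behind the sensitivity:
a linear per-unit sensitivity extrapolated past the dose range that
produced it (e.g. dose-response curves that saturate) is a prediction of
convenience, not of confidence.

## The synthetic generator

`generate_observations()` draws tables that emulate the compiled
literature's structure: studies (one site each) nested within factors, a
configurable number of species per site and replicate observations per
species, a unit-level random effect with the configured τ², one treatment
magnitude per study drawn uniformly from factor-specific native ranges,
log-normal control conductances, and reported standard errors from a
constant coefficient of variation (`SE = cv·mean/√n`), so the computed
`v_within` equals the true measurement-noise variance by construction.
Default parameters are chosen to be realistic for this literature: true
mean sensitivities of −8.3, −1.5, +2.1, −3.5, +0.8, −2.1 % per
standardized unit for eCO2, eT, iP, dP, eN, eO3; τ² = 0.02 per factor;
magnitude ranges of +200–400 ppm, +1–5 °C, 20–60 % precipitation,
2–15 g N, 20–80 ppb O3; control g_s median 0.25 mol m⁻² s⁻¹; replicate
counts 3–10; `se_cv = 0.15`; 85 % outdoor studies. Heterogeneity can be
placed on the sensitivity scale (default — biologically, species differ in
per-unit responsiveness) or on the lnRR scale (convenient when a
simulation needs a constant true pooled mean). Optional components add a
saturating dose-response (`plateau`), per-biome sensitivity offsets,
complete factorial triples obeying
`lnRR_ab = λ(lnRR_a + lnRR_b)` with measurement noise, and a small-study
suppression switch that censors rows falling below the factor's true mean
when their variance is above the median — the classic asymmetry mechanism
for bias-test power checks. Identical configurations generate identical
tables, and generation restores the caller's RNG stream.

What the generator does *not* emulate — and what passing recovery tests
therefore cannot certify about real data: the real dataset's uneven
species/biome frequencies, correlated moderators (magnitude confounded
with duration, climate with biome), shared control arms across
observations of one study, non-normal measurement error in digitised
figures, and selective reporting subtler than the censoring switch.

## Simulation sizes and numerical checks

The recovery checks in the test suite use panel sizes chosen to balance
statistical resolution against runtime: coverage and τ² recovery on 200
panels of k = 400 (fixed dose, lnRR-scale heterogeneity, independent
units — the weight adjustment is deliberately conservative for replicated
units, so nominal coverage is assessed on the design where it is defined);
slope-test calibration on 1000 null panels of k = 150 and slope recovery
at k = 300; interaction recovery on 200 triples with `se_cv = 0.05` and
n = 8–12; Egger calibration on 200 panels of k = 500 with τ² = 0 (the
exact-null design for the classic test) and power on ~300-observation
suppressed panels. Exact-algebra identities (antisymmetry, scale
invariance, `w*·n_ob = w`, `lnSens·Δ = lnRR`, percentage round-trip) are
asserted at machine precision, and pooling is verified against a
brute-force loop implementation of the defining sums at 1e-12.

## Known limitations

* The weight adjustment `w* = w/n_ob` treats each species-site unit as one
  observation but does not model the full covariance of shared controls; a
  hierarchical model with explicit study-level random effects is out of
  scope.
* The interaction trend is not corrected for errors in the summed-effect
  axis; with noisy arms its slope is attenuation-biased.
* Q_B with a common τ² assumes the heterogeneity is exchangeable across
  groups; `tau2_scope = "within"` is available but the two choices can
  disagree when group sizes are very unbalanced.
* Projections are per-factor only; combining factors would require the
  interaction structure the projection stage deliberately does not model.
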