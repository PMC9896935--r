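---
title: "Biological age estimation and Gompertz mortality modelling: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Biological age estimation and Gompertz mortality modelling: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bioage)
```

## The estimation problem

A cohort supplies, per subject, chronological age at baseline `CA`
(years), a panel of `J ≥ 3` biomarkers, follow-up duration `t` (years)
and a death indicator. Biological age `BA` is conceived as a latent
indicator of accumulated physiological deterioration, expressed in years
on the CA scale; the working quantity downstream is the gap
`ΔBA = BA − CA`, positive for subjects biologically older than their
calendar age. The package implements three established estimators (MLR,
PCA, Klemera–Doubal) and two estimators built on a one-factor structural
equation model (SEM): outcome-free (OF) and outcome-dependent (OD,
anchored on mortality). All five run on the same filtered cohort and
marker set, so their BA distributions and predictive performance are
directly comparable.

## Eligibility filters

The analysis view keeps subjects aged 30–75 at baseline with complete
age and marker data. The lower and upper age bounds focus the model on
adult mortality and limit survivor-selection bias at the oldest ages.
Deaths from HIV, violence or accidents are not plausibly driven by
age-related deterioration; by default they are **recoded as censored at
the observed duration** rather than deleted, which preserves the
subject's exposure time — the standard competing-cause convention. A
switch (`excluded_deaths = "drop"`) removes the rows instead, for
sensitivity analysis. Filtering is complete-case only; no imputation is
attempted, and durations are taken as a precomputed column.

## The one-factor SEM

The measurement and structural equations are

```
x_j = ν_j + λ_j · BA + ε_j,   ε_j ~ N(0, θ_j)
BA  = c + b · g(CA) + ζ,      ζ   ~ N(0, ψ)
```

with `g` the identity ("linear") or the natural log ("loglinear").

**Identification.** The latent scale is pinned by the reference-indicator
convention: `λ₁ = 1` *and* `ν₁ = 0` (the structural intercept `c` and
the full set of marker intercepts are not jointly identified, so the
first marker's intercept is sacrificed). The latent factor therefore
carries the first marker's units. This choice is immaterial downstream:
factor scores enter every BA estimator only through an OLS calibration,
and OLS fitted values are invariant to affine maps of the regressor —
the property the test suite asserts directly by rescaling markers and
comparing OF BA to 1e-6.

**Estimation.** With complete data, the Gaussian likelihood depends on
the sample only through the mean vector and covariance matrix of
`(x₁..x_J, g(CA))`, so each evaluation costs a single `(J+1)×(J+1)`
Cholesky factorization regardless of `n`. The exogenous `g(CA)` block is
saturated at the sample moments. Optimization is BFGS over
`(ν₂..ν_J, λ₂..λ_J, log θ, c, b, log ψ)` — variances on the log scale,
which enforces positivity without constraints — started from a
principal-axis decomposition of the marker covariance (first eigenvector
scaled to the reference marker, communality-based residual variances),
with up to five 10%-jittered restarts on non-convergence and relative
tolerance 1e-14. Degenerate inputs fail early with named errors: fewer
than three markers, a zero-variance marker, non-positive ages under the
log form.

**Reported likelihood.** The stored log-likelihood is the *conditional*
likelihood of the markers given `g(CA)` (joint minus the saturated
exogenous marginal). This matters for one comparison: the linear and
log-linear forms condition on different transformations of age, and only
the conditional likelihoods score the same data (the markers). AIC/BIC
across the two forms are therefore like-for-like; on data generated from
the linear structural truth the linear form wins both, which the suite
checks. Parameter count is `3J + 1`; SRMR is computed from the
correlation-scale residuals of the fitted versus observed joint
covariance.

**Factor scores.** Regression-method (expected a posteriori) scores,
`FS = E[BA | x, g(CA)]` under the fitted Gaussian model. Bartlett scores
differ from these only affinely in a one-factor model, so BA downstream
would be unchanged; the regression scores are the ones computed.

## The five estimators

- **MLR**: fitted values of OLS of CA on all markers. The BA-on-CA slope
  equals the model R² exactly (an OLS identity, asserted to 1e-10),
  which is why MLR always compresses BA toward the cohort mean age.
- **PCA**: first principal component of z-scored markers, sign-aligned
  to correlate positively with CA, then `BA = mean(CA) + PC1_z·SD(CA)`.
  The mean/SD mapping is chosen over regressing CA on PC1 because the
  latter would force the PCA BA variance below the CA variance, whereas
  matching the age SD preserves a dispersion comparable to or larger
  than other estimators' — the behaviour expected of PCA-based BA.
- **KD**: per-marker calibrations `x_j = q_j + k_j·CA + e_j` (slope,
  intercept, residual SD `s_j`, correlation `r_j`), combined as an
  inverse-variance weighted age, then shrunk toward CA with weight
  `1/s_BA²`. The default `s_BA²` is
  `max(1e-6, mean[(BA_E − CA)²] − ((1 − r̄²)/r̄²)·(CA_max − CA_min)²/(12J))`
  with `r̄` the mean absolute marker–age correlation — the sampling
  variance of the uncorrected estimator netted out of its dispersion
  around CA; a user-supplied `s_ba2` overrides it. Markers numerically
  uncorrelated with age, or with residual SD at rounding-error scale
  (an exact function of age would otherwise receive infinite weight),
  are excluded with a warning. Because both calibration and estimation
  happen in-sample, the OLS of KD BA on CA has slope 1 and intercept 0
  up to floating-point error — marker residuals are orthogonal to CA by
  construction, and the corrected estimator is a fixed-weight convex
  combination of two quantities each regressing on CA with unit slope.
- **OF**: OLS of CA (linear) or ln CA (log-linear) on FS; fitted values
  (exponentiated in the log case, deliberately without a
  retransformation correction, so the estimate stays the median-scale
  back-transform) are BA. The calibration reports Wald tests of
  intercept 0 / slope 1 (linear) or 1 / 1 (log-linear) — the nulls under
  which the SEM estimator collapses to the restricted forms the older
  methods assume.
- **OD**: two constrained Gompertz fits — null (baseline age only) and
  augmented (adds FS) — define BA as the age whose null hazard equals
  the subject's augmented hazard:
  `BA = [ln(k_a/k_n) + β_a·CA + γ·FS]/β_n`. The identity is read as
  *null hazard at the candidate age* = *augmented hazard at the actual
  (CA, FS)*. The alternative literal reading (augmented hazard also
  evaluated at the candidate age) degenerates when `γ = 0`: any age
  would satisfy it, contradicting the requirement that OD collapse to
  `BA = CA` exactly when scores carry no hazard information. The
  implemented form has that collapse bit-exactly, and agrees with a
  numeric root-finder on the identity to 1e-9 over a thousand random
  parameter draws. For the "nonlinear" OD variant the scores from the
  log-linear SEM enter the same identity; the hazard stays Gompertz in
  age.

## Gompertz hazard engine

The hazard is `μ_i(t) = k·exp(β·CA_i + β·t + x_i'θ)` with right-censored
log-likelihood `ℓ = Σ d_i ln μ_i(t_i) − H_i(t_i)`,
`H_i(t) = (k/β)e^{β CA_i + x_i'θ}(e^{βt} − 1)`. The equality of the
baseline-age and duration coefficients is imposed *structurally* — one
parameter serves both roles — so the constraint holds bit-exactly rather
than approximately through a penalty; an unconstrained variant frees a
separate `α` for baseline age. Optimization is BFGS over `(ln k, β, θ)`
with the analytic gradient (`∂ℓ/∂ln k = Σ(d_i − H_i)` and kin), started
from `β = 0.08` and a level matching the expected death count, followed
by one Newton polish step on the observed information. Standard errors
are observed-information Wald on the working scale, delta-method
back-transformed for `k` (its CI is computed on the log scale, keeping
it positive). Doubling time is `ln 2/β`; hazard ratios `exp(coef)`;
AIC/BIC use the subject count `n`.

## Evaluation layer

**Life expectancy.** `E(age) = ∫₀^ω S(t)dt` with
`S(t) = exp(−(k/β)e^{β·age + φ·Δ}(e^{βt} − 1))`, adaptive quadrature at
relative tolerance 1e-8 and upper limit `ω = 120 − age` (human mortality
beyond 120 contributes nothing at these hazards). The scenario table
reports differences against `Δ = 0`; with `φ > 0` the differences fall
only in the biologically-older-lose / biologically-younger-gain
quadrants. The quadrature is validated against both a step-0.001
trapezoid and an upper-incomplete-gamma closed form.

**AUC.** The full AUC is the midrank Mann–Whitney statistic (ties get
half credit). The partial AUC over a specificity band `(lo, hi)` is the
exact area of the empirical ROC polyline clipped to false-positive rates
`[1 − hi, 1 − lo]` — vertical segments contribute nothing, tie
diagonals integrate as trapezoids — normalized by band width so a
perfect classifier scores 1 on any band (the raw area is attached as an
attribute). Risk scores for mortality ROC are model-predicted cumulative
hazards at a fixed horizon; subjects censored before the horizon are
dropped (their label at the horizon is unknown), deaths by the horizon
are positives, subjects still observed at the horizon negatives.

**Disparity models.** OLS of ΔBA on age plus categorical sex,
race/ethnicity and education with explicit reference levels, reporting
coefficients, adjusted R², AIC and BIC, one column per estimator when
several are supplied.

## The synthetic cohort

The generator emulates exactly the structure the estimators assume: ages
uniform on 30–75; a latent deterioration factor `L = a + b·CA + ζ`;
markers `x_j = ν_j + λ_j·L + ε_j`; survival times drawn by inverse-CDF
from `μ(t) = k·exp(β·(CA + t) + γ·z)` with `z` the standardized latent
(so `γ` is per SD of deterioration, matching the unitless character of
factor scores), administratively censored at 25 years — the middle of a
21–27-year follow-up window typical of linked-mortality cohort studies.

Default truth: `n = 5000`, nine markers with loadings
`(1.0, 0.9, 0.8, 0.7, 0.6, 0.5, 0.4, −0.6, −0.8)` — the two negative
loadings mirror markers such as forced expiratory volume and albumin
where higher is better — unit residual SDs, `k = 1e-4` per year,
`β = 0.09` per year, `γ = 1.5` per SD. The structural slope and
disturbance are the one place the defaults were genuinely open: `a = 0`,
`b = 0.05` per year and `ψ = b·SD(Unif(30,75)) ≈ 0.65` make age explain
half the latent variance and put marker–age correlations in the 0.3–0.5
range typical of real biomarker panels. One integer seed governs every
draw; identical seeds give bit-identical cohorts.

What the generator does *not* emulate — and hence what passing tests do
not establish about field data: non-Gaussian and skewed marker
distributions, nonlinear marker–age trajectories, time-varying
biomarkers, competing risks beyond the single censored-cause flag,
frailty beyond one latent factor, and survey design effects. Recovery
results here validate the estimators under their own assumptions, not
their robustness to violations.

## Numerical choices and test design

- SEM: log-scale variances, reltol 1e-14, 5 jittered restarts;
  `(J+1)`-dimensional Cholesky per evaluation. Gompertz: analytic
  gradient, Newton polish, convergence declared at gradient norm < 1e-3
  if the optimizer's own flag fails.
- Quadrature tolerance 1e-8; OD root agreement 1e-9; exact-identity
  assertions at 1e-10 to 1e-12.
- Monte-Carlo recovery checks run 20 seeded simulations at `n = 5000`
  and compare the mean estimate to truth within twice the *per-replicate*
  Monte-Carlo SE (the SD across seeds). Maximum likelihood at fixed `n`
  carries O(1/n) bias — the SEM loading bias halves and more when `n`
  grows tenfold — so a criterion based on the SE of the *mean* would
  tighten indefinitely with more seeds and fail any consistent estimator
  at fixed `n`; the per-replicate SE is the scale on which a single
  study's estimate is expected to recover truth.
- Problem sizes in the suite (n = 400–20,000, 10–20 seeds where
  replicated) were chosen to keep every Monte-Carlo band informative
  while the whole suite runs in well under a minute.

## Known limitations

- Analytic `n` differs across published NHANES analyses of this design
  (complete-marker versus complete-covariate samples); the package
  reports filter counts explicitly rather than guessing a single rule.
- The OD estimator inherits any misspecification of the Gompertz
  baseline; no Makeham term, frailty or spline baseline is offered.
- KD's `s_BA` recipe is one defensible reconstruction of the original
  two-step method's dispersion correction; supplying `s_ba2` directly is
  recommended when comparability with a specific published calibration
  matters.
- Marker-subset sensitivity (how BA shifts when panels are reduced) is
  out of scope.
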