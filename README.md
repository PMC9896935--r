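# bioage

Biological age (BA) estimation from biomarker panels, and Gompertz
mortality modelling of accelerated aging.

## The problem

Chronological age (CA) is only a crude proxy for the latent physiological
deterioration that drives morbidity and mortality. Given a cohort with
baseline age, a panel of biomarkers (lung, metabolic, cardiovascular,
renal markers, ...) and right-censored mortality follow-up, this package
computes per-subject biological age by five methods and then uses the gap
ΔBA = BA − CA in parametric hazard models to quantify accelerated aging.
It is written for population-health and biodemography researchers working
with NHANES-style cohort files, and ships a synthetic-cohort simulator
with known truth so the entire workflow can be exercised and validated
without any external data.

## Methods

**Classic estimators**

- **MLR** — OLS of CA on all markers; fitted values are BA. The BA-on-CA
  slope then equals the regression R², always below 1.
- **PCA** — first principal component of the z-scored markers,
  sign-aligned with CA and mapped to age units:
  `BA = mean(CA) + PC1_z · SD(CA)`.
- **KD (Klemera–Doubal)** — per-marker regressions `x_j = q_j + k_j·CA`
  combined by inverse residual variance,

  `BA = [ Σ_j (x_j − q_j) k_j/s_j² + CA/s_BA² ] / [ Σ_j (k_j/s_j)² + 1/s_BA² ]`.

**SEM-based estimators** (the package's core). A one-factor structural
equation model treats BA as a latent variable measured by the biomarkers
and linked to age:

```
x_j = ν_j + λ_j·BA + ε_j        (measurement)
BA  = c + b·g(CA) + ζ           (structural; g = identity or log)
```

fitted by maximum likelihood, with regression-method factor scores
FS = E[BA | markers, g(CA)].

- **OF (outcome-free)** — OLS of CA (or ln CA) on FS; fitted values are
  BA. Wald tests of intercept 0 / slope 1 check whether the restricted
  functional forms of the older methods are tenable.
- **OD (outcome-dependent)** — anchored on mortality. Fit a null Gompertz
  hazard `μ = k·exp(β·CA₀)·exp(β·t)` and an augmented one that adds
  `exp(γ·FS)`, then define BA as the age at which the null hazard equals
  the subject's augmented hazard:

  `BA = [ln(k_a/k_n) + β_a·CA + γ·FS] / β_n`.

**Mortality modelling.** Constrained Gompertz proportional hazards with
right censoring (the baseline-age coefficient structurally equal to the
duration slope β), covariate effects γ (per unit FS) and φ (per year of
ΔBA), mortality-rate doubling time `ln 2/β`, remaining life expectancy
E(65) by quadrature of the survival function, and full/partial AUC for
mortality prediction.

## Worked example

```r
library(bioage)

truth <- synthetic_truth(n = 2000, seed = 42L)   # known generating model
sim   <- simulate_cohort(truth)
ch    <- apply_eligibility_filters(sim$cohort)   # ages 30-75, complete cases

sem <- fit_sem(ch)
fs  <- factor_scores(sem, ch)

null_fit <- fit_gompertz(ch)
aug_fit  <- fit_gompertz(ch, covariates = list(fs = as.numeric(fs)))
print(null_fit)
print(aug_fit)
```

```
<gompertz_fit> n = 2000, events = 1160, baseline age coef = duration coef
  k = 7.95e-05 (95% CI 5.41e-05, 0.000117)
  beta = 0.0978 (doubling time 7.1 y)
  loglik = -4307.9, AIC = 8619.8, BIC = 8631.0
<gompertz_fit> n = 2000, events = 1160, baseline age coef = duration coef
  k = 6.42e-09 (95% CI 2.97e-09, 1.39e-08)
  beta = 0.0693 (doubling time 10.0 y)
  fs = 1.4628 (SE 0.0466)
  loglik = -3815.7, AIC = 7637.4, BIC = 7654.2
```

Adding the factor scores flattens the duration slope from 0.098 to 0.069
— the doubling time stretches from 7.1 to 10.0 years — because part of
the apparent age-acceleration of mortality is deterioration that the
biomarkers capture. The acceleration decomposition of the augmented
model is exactly the quantity of interest.

```r
od <- estimate_od(fs, ch, null_fit, aug_fit, "linear")
for (e in list(estimate_mlr(ch), estimate_pca(ch), estimate_kd(ch),
               estimate_of(fs, ch, "linear")$estimates, od))
  cat(sprintf("%-10s slope of BA on CA: %.3f\n",
              e$method, ba_ca_regression(e, ch)$slope))
```

```
MLR        slope of BA on CA: 0.395
PCA        slope of BA on CA: 0.625
KD         slope of BA on CA: 1.000
OF-linear  slope of BA on CA: 0.585
OD-linear  slope of BA on CA: 1.459
```

KD reproduces its built-in unit-slope constraint; MLR/PCA/OF compress BA
toward the mean age; only the outcome-dependent estimator yields a slope
above 1, the signature of accelerated biological aging relative to
calendar time.

```r
gap <- fit_gompertz(ch, covariates = list(delta = od$delta))
e65_delta_curve(gap, delta_grid = c(-5, -2, 0, 2, 5))
```

```
  age delta         e    e_diff
1  65    -5 15.680861  3.669488
2  65    -2 13.416846  1.405472
3  65     0 12.011373  0.000000
4  65     2 10.693361 -1.318012
5  65     5  8.886305 -3.125069
```

A subject five years biologically older than their calendar age loses
about 3.1 years of remaining life expectancy at 65 under this fitted
model; five years younger gains about 3.7.

The same workflow runs end to end from the shell:

```sh
Rscript exec/bioage run --out results/run1 --seed 42
```

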