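Package: bioage
Title: Biological Age Estimation and Gompertz Mortality Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates biological age (BA) from a cohort's chronological
    ages and a biomarker panel by five methods: multiple linear regression
    (MLR), principal components (PCA), the Klemera-Doubal two-step
    estimator (KD), and two structural-equation-model based estimators --
    outcome-free (OF, linear and log-linear) and outcome-dependent (OD,
    anchored on mortality). Fits constrained Gompertz proportional-hazard
    models with right censoring to quantify accelerated aging
    (mortality-rate doubling times, hazard effects of the BA-CA gap, life
    expectancy at 65, full and partial AUC), and ships a synthetic-cohort
    simulator with known truth so every stage is testable without external
    data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    haven,
    pROC,
    flexsurv,
    pracma
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
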