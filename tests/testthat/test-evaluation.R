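test_that("life expectancy matches brute-force and incomplete-gamma oracles", {
  fit <- fake_gfit(1e-5, 0.1, phi = 0)
  e <- life_expectancy(fit, 65, 0)
  # brute force: trapezoid at step 0.001
  tt <- seq(0, 55, by = 0.001)
  lev <- (1e-5 / 0.1) * exp(0.1 * 65)
  s <- exp(-lev * expm1(0.1 * tt))
  brute <- sum(diff(tt) * (head(s, -1) + tail(s, -1)) / 2)
  expect_equal(e, brute, tolerance = 1e-4)

  skip_if_not_installed("pracma")
  # change of variable u = c e^{bt}: E = (e^c/b) [E1(c) - E1(c e^{b omega})]
  closed <- (exp(lev) / 0.1) *
    (pracma::expint_E1(lev) - pracma::expint_E1(lev * exp(0.1 * 55)))
  expect_equal(e, closed, tolerance = 1e-6)
})

test_that("E(65) scenario differences fall in the expected quadrants", {
  fit <- fake_gfit(1e-4, 0.09, phi = 0.1)
  e0 <- life_expectancy(fit, 65, 0)
  expect_lt(life_expectancy(fit, 65, 5), e0)
  expect_gt(life_expectancy(fit, 65, -5), e0)
  tab <- e65_delta_curve(fit)
  expect_equal(tab$e_diff[tab$delta == 0], 0)
  expect_true(all(sign(tab$e_diff) == -sign(tab$delta * 0.1) |
                    tab$delta == 0))
  expect_true(all(tab$e > 0))
  # a null gap coefficient produces a flat curve
  flat <- e65_delta_curve(fake_gfit(1e-4, 0.09, phi = 0))
  expect_equal(flat$e_diff, rep(0, nrow(flat)), tolerance = 1e-10)
  # a steeper coefficient produces uniformly larger losses
  steep <- e65_delta_curve(fake_gfit(1e-4, 0.09, phi = 0.25))
  off0 <- tab$delta != 0
  expect_true(all(abs(steep$e_diff[off0]) > abs(tab$e_diff[off0])))
})

test_that("full AUC equals the Mann-Whitney statistic and a reference implementation", {
  set.seed(7)
  scores <- rnorm(500)
  labels <- rbinom(500, 1, plogis(scores))
  auc <- roc_auc(scores, labels)
  w <- wilcox.test(scores[labels == 1], scores[labels == 0],
                   exact = FALSE)$statistic
  expect_equal(as.numeric(auc),
               unname(w) / (sum(labels) * sum(1 - labels)),
               tolerance = 1e-12)
  skip_if_not_installed("pROC")
  ref <- pROC::auc(pROC::roc(labels, scores, quiet = TRUE))
  expect_equal(as.numeric(auc), as.numeric(ref), tolerance = 1e-12)
})

test_that("partial AUC is band-normalized and matches pROC's raw area", {
  # perfect separation scores 1 on any band
  scores <- c(1:10 / 10, 2 + 1:10 / 10)
  labels <- rep(c(0, 1), each = 10)
  expect_equal(as.numeric(roc_auc(scores, labels)), 1)
  expect_equal(as.numeric(roc_auc(scores, labels, c(0.8, 0.9))), 1)
  expect_equal(as.numeric(roc_auc(scores, labels, c(0, 0.5))), 1)

  set.seed(11)
  scores <- rnorm(800)
  labels <- rbinom(800, 1, plogis(2 * scores))
  for (band in list(c(0.8, 0.9), c(0.9, 1), c(0.4, 0.7))) {
    got <- roc_auc(scores, labels, band)
    raw <- attr(got, "raw_area")
    expect_equal(as.numeric(got), raw / diff(band), tolerance = 1e-12)
    skip_if_not_installed("pROC")
    ref <- pROC::auc(pROC::roc(labels, scores, quiet = TRUE),
                     partial.auc = band,
                     partial.auc.focus = "specificity",
                     partial.auc.correct = FALSE)
    expect_equal(raw, as.numeric(ref), tolerance = 1e-9)
  }
})

test_that("uninformative scores score near one half and single-class input errors", {
  set.seed(3)
  scores <- rnorm(10000)
  labels <- rbinom(10000, 1, 0.3)
  expect_lt(abs(as.numeric(roc_auc(scores, labels)) - 0.5), 0.02)
  expect_error(roc_auc(scores, rep(1, 10000)), "both outcome classes")
})

test_that("risk scores are cumulative hazards with horizon-consistent labels", {
  fx <- default_fixture()
  fit <- fit_gompertz(fx$cohort)
  rs <- mortality_risk_score(fit, fx$cohort, horizon = 20)
  i <- 17
  expected <- (fit$k / fit$beta) * exp(fit$beta * fx$cohort$ca_t0[i]) *
    expm1(fit$beta * 20)
  expect_equal(rs$score[i], expected, tolerance = 1e-12)
  expect_true(all(is.na(rs$label[fx$cohort$dead == 0 &
                                   fx$cohort$duration < 20])))
  ok <- !is.na(rs$label)
  # deaths carry higher model risk than survivors on average
  expect_gt(as.numeric(roc_auc(rs$score[ok], rs$label[ok])), 0.6)
})

test_that("BA-on-CA regression reproduces identities and the KD non-rejection", {
  ca <- seq(30, 75, length.out = 40)
  ch <- toy_cohort(ca, data.frame(m1 = ca * 1.1, m2 = rev(ca)))
  ident <- suppressWarnings(  # exact fit by construction
    ba_ca_regression(ba_estimates("KD", ca, ca), ch))
  expect_equal(ident$slope, 1, tolerance = 1e-12)
  expect_equal(ident$intercept, 0, tolerance = 1e-12)

  # KD assumptions make the (0, 1) null essentially untestable: across
  # seeded cohorts the Wald battery should fail to reject at alpha = .05
  rejections <- vapply(1:10, function(s) {
    sim <- simulate_cohort(synthetic_truth(n = 1000, seed = 1000L + s))
    ch <- apply_eligibility_filters(sim$cohort)
    reg <- ba_ca_regression(estimate_kd(ch), ch)
    any(reg$wald$p < 0.05)
  }, logical(1))
  expect_gte(mean(!rejections), 0.9)
})

test_that("disparity regressions recover an injected group offset", {
  fx <- default_fixture()
  kd <- estimate_kd(fx$cohort)
  # no injected effects: group coefficients within 2 SEs of zero
  res0 <- disparity_regression(kd, fx$cohort)
  grp <- grep("race|sex|education", rownames(res0$coefficients))
  expect_true(all(abs(res0$coefficients[grp, 1]) <
                    2 * res0$coefficients[grp, 2]))

  # +2 y of biological aging injected for one group
  shifted <- kd
  hit <- fx$cohort$race == "nh_black"
  shifted$ba <- shifted$ba + 2 * hit
  shifted <- delta_ba(shifted, fx$cohort)
  res <- disparity_regression(shifted, fx$cohort)
  est <- res$coefficients["racenh_black", 1]
  se <- res$coefficients["racenh_black", 2]
  expect_lt(abs(est - 2), 2 * se)
  expect_error(disparity_regression(kd, fx$cohort,
                                    covariates = list(race = "martian")),
               "martian")
})

test_that("the multi-method disparity table keeps the requested method order", {
  fx <- default_fixture()
  ests <- list(estimate_kd(fx$cohort), estimate_mlr(fx$cohort),
               estimate_pca(fx$cohort))
  tab <- disparity_regression(ests, fx$cohort)
  expect_equal(names(tab), c("term", "KD", "MLR", "PCA"))
  expect_true(all(c("adj_r_squared", "aic", "bic", "n") %in% tab$term))
})
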