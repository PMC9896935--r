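test_that("MLR reproduces CA exactly when markers determine age without noise", {
  ca <- c(31, 40, 48, 55, 61, 70, 74, 36)
  # two markers that are both exact affine images of age are mutually
  # collinear -> rank deficiency
  ch <- toy_cohort(ca, data.frame(m1 = 2 * ca + 1, m2 = -0.5 * ca + 3))
  expect_error(estimate_mlr(ch), "rank deficient")
  ch <- toy_cohort(ca, data.frame(m1 = 2 * ca + 1, m2 = ca^2 / 10))
  mlr <- estimate_mlr(ch)
  expect_equal(mlr$ba, ca, tolerance = 1e-10)
})

test_that("MLR slope on CA equals the regression R-squared (normal-equations oracle)", {
  fx <- default_fixture()
  mlr <- estimate_mlr(fx$cohort)
  reg <- ba_ca_regression(mlr, fx$cohort)
  # independent oracle: solve the normal equations by hand
  X <- cbind(1, marker_matrix(fx$cohort))
  y <- fx$cohort$ca_t0
  bhat <- solve(crossprod(X), crossprod(X, y))
  fitted <- drop(X %*% bhat)
  r2 <- 1 - sum((y - fitted)^2) / sum((y - mean(y))^2)
  expect_equal(mlr$ba, unname(fitted), tolerance = 1e-8)
  expect_equal(reg$slope, r2, tolerance = 1e-10)
  expect_gt(cor(mlr$ba, y), 0)
})

test_that("MLR is a perfect-fit identity when markers are exact functions of age", {
  ca <- seq(30, 75, length.out = 12)
  ch <- toy_cohort(ca, data.frame(m1 = 0.8 * ca - 2))
  mlr <- estimate_mlr(ch)
  expect_equal(mlr$ba, ca, tolerance = 1e-10)
  expect_equal(mlr$delta, rep(0, 12), tolerance = 1e-10)
})

test_that("PCA BA matches the age distribution moments and a hand-computed 2x2 eigenvector", {
  fx <- default_fixture()
  pca <- estimate_pca(fx$cohort)
  expect_equal(mean(pca$ba), mean(fx$cohort$ca_t0), tolerance = 1e-10)
  expect_equal(sd(pca$ba), sd(fx$cohort$ca_t0), tolerance = 1e-10)

  # 4-subject, 2-marker toy against the closed-form eigendecomposition of
  # the 2x2 correlation matrix (quadratic formula: eigenvector (1, 1)/sqrt2
  # for positive correlation)
  ca <- c(30, 44, 59, 70)
  m <- data.frame(m1 = c(0.2, 1.1, 2.3, 3.1), m2 = c(5, 9, 12, 19))
  ch <- toy_cohort(ca, m)
  pca <- estimate_pca(ch)
  z <- scale(as.matrix(m))
  pc1 <- drop(z %*% c(1, 1) / sqrt(2))
  if (cor(pc1, ca) < 0) pc1 <- -pc1
  expected <- mean(ca) + (pc1 / sd(pc1)) * sd(ca)
  expect_equal(pca$ba, expected, tolerance = 1e-10)
})

test_that("two perfectly correlated markers load on a single component", {
  ca <- c(35, 45, 55, 65)
  m1 <- c(1, 2, 3, 4)
  ch <- toy_cohort(ca, data.frame(m1 = m1, m2 = 3 * m1 - 2))
  ev <- eigen(cor(marker_matrix(ch)))$values
  expect_equal(ev[1] / sum(ev), 1, tolerance = 1e-12)
  expect_error(estimate_pca(ch), NA)
})

test_that("PCA BA is invariant to marker order and single-marker sign flips", {
  fx <- default_fixture()
  base <- estimate_pca(fx$cohort)
  df <- as.data.frame(fx$cohort)
  mk <- rev(marker_names(fx$cohort))
  ch_rev <- cohort(df, markers = mk)
  expect_equal(estimate_pca(ch_rev)$ba, base$ba, tolerance = 1e-10)
  df2 <- df
  df2$marker02 <- -df2$marker02
  ch_flip <- cohort(df2, markers = marker_names(fx$cohort))
  expect_equal(estimate_pca(ch_flip)$ba, base$ba, tolerance = 1e-10)
})

test_that("KD calibration recovers the marginal regressions and flags degenerate markers", {
  ca <- seq(30, 75, by = 5)
  ch <- toy_cohort(ca, data.frame(m1 = 0.5 * ca + 10))
  # an exact linear marker drives s_j -> 0: degenerate guard
  expect_error(suppressWarnings(kd_calibrate(ch)), "no usable markers")

  fx <- default_fixture()
  cal <- kd_calibrate(fx$cohort)
  expect_true(all(cal$usable))
  expect_true(all(cal$s > 0))
  expect_true(all(abs(cal$r) <= 1))
  expect_gt(cal$s_ba, 0)
  # fitted slopes carry the sign of loading x structural slope
  expect_equal(sign(unname(cal$k)),
               sign(fx$truth$loadings * fx$truth$struct_slope))
})

test_that("KD calibration on an age subset stays finite", {
  fx <- default_fixture()
  sub <- fx$cohort[fx$cohort$ca_t0 >= 40 & fx$cohort$ca_t0 <= 60, ]
  sub <- cohort(as.data.frame(sub), markers = marker_names(fx$cohort))
  cal <- kd_calibrate(sub)
  expect_true(all(is.finite(cal$k)))
  expect_true(all(is.finite(cal$q)))
  expect_true(is.finite(cal$s_ba))
})

test_that("KD point estimates match direct arithmetic of the weighted-sum formula", {
  # single marker: a subject sitting exactly on the calibration line at 60
  cal <- structure(list(q = c(m1 = 10), k = c(m1 = 0.5), s = c(m1 = 2),
                        r = c(m1 = 0.9), usable = c(m1 = TRUE), s_ba = 8,
                        age_range = c(30, 75)),
                   class = "kd_calibration")
  ch <- toy_cohort(c(40, 50, 55), data.frame(m1 = c(10 + 0.5 * 60, 35, 36)))
  kd_e <- attr(estimate_kd(ch, cal), "ba_e")
  expect_equal(kd_e[1], 60, tolerance = 1e-12)

  # 3-subject, 2-marker toy: oracle = direct arithmetic
  cal2 <- structure(list(q = c(a = 2, b = -1), k = c(a = 0.4, b = 0.2),
                         s = c(a = 1.5, b = 3), r = c(a = 0.8, b = 0.5),
                         usable = c(a = TRUE, b = TRUE), s_ba = 10,
                         age_range = c(30, 75)),
                    class = "kd_calibration")
  m <- data.frame(a = c(20, 25, 31), b = c(8, 10.5, 13))
  ch2 <- toy_cohort(c(45, 58, 71), m)
  got <- attr(estimate_kd(ch2, cal2), "ba_e")
  oracle <- vapply(1:3, function(i) {
    num <- (m$a[i] - 2) * 0.4 / 1.5^2 + (m$b[i] + 1) * 0.2 / 3^2
    den <- (0.4 / 1.5)^2 + (0.2 / 3)^2
    num / den
  }, numeric(1))
  expect_equal(got, oracle, tolerance = 1e-12)
  # corrected estimator shrinks toward CA with weight 1/s_BA^2
  corr <- estimate_kd(ch2, cal2)$ba
  oracle_corr <- vapply(1:3, function(i) {
    num <- (m$a[i] - 2) * 0.4 / 1.5^2 + (m$b[i] + 1) * 0.2 / 3^2 +
      c(45, 58, 71)[i] / 100
    den <- (0.4 / 1.5)^2 + (0.2 / 3)^2 + 1 / 100
    num / den
  }, numeric(1))
  expect_equal(corr, oracle_corr, tolerance = 1e-12)
})

test_that("KD biological age regresses on CA with unit slope and zero intercept", {
  fx <- default_fixture()
  kd <- estimate_kd(fx$cohort)
  reg <- ba_ca_regression(kd, fx$cohort)
  expect_equal(reg$slope, 1, tolerance = 1e-8)
  expect_equal(reg$intercept, 0, tolerance = 1e-6)
})
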