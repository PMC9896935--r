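#' Container for biological-age estimates
#'
#' @param method Method tag, one of `"MLR"`, `"PCA"`, `"KD"`,
#'   `"OF-linear"`, `"OF-nonlinear"`, `"OD-linear"`, `"OD-nonlinear"`.
#' @param ba Numeric vector of biological ages (years).
#' @param ca Numeric vector of chronological ages (years), same length.
#' @return Object of class `ba_estimates` with fields `method`, `ba` and
#'   `delta` (= BA - CA, exact elementwise difference).
#' @export
ba_estimates <- function(method, ba, ca) {
  if (length(ba) != length(ca)) stop("ba and ca lengths differ")
  if (any(!is.finite(ba))) stop("non-finite BA estimates")
  structure(list(method = method, ba = unname(as.numeric(ba)),
                 delta = unname(as.numeric(ba - ca))),
            class = "ba_estimates")
}

#' @export
print.ba_estimates <- function(x, ...) {
  cat(sprintf("<ba_estimates> %s, n = %d; BA mean %.2f y (SD %.2f), mean delta %+.2f y\n",
              x$method, length(x$ba), mean(x$ba), stats::sd(x$ba),
              mean(x$delta)))
  invisible(x)
}

#' Populate the BA - CA difference
#'
#' @param ba A [ba_estimates()].
#' @param x The cohort the estimates belong to.
#' @return `ba` with `delta` recomputed as the exact elementwise
#'   difference BA - CA.
#' @export
delta_ba <- function(ba, x) {
  stopifnot(inherits(ba, "ba_estimates"), inherits(x, "cohort"))
  if (length(ba$ba) != nrow(x)) stop("estimate/cohort length mismatch")
  ba$delta <- ba$ba - x$ca_t0
  ba
}

#' Multiple-linear-regression biological age
#'
#' Ordinary least squares of chronological age on all biomarkers; the
#' fitted values are the BA estimates. By a standard OLS identity, the
#' slope of BA on CA equals the regression R-squared, which is why MLR
#' compresses BA toward the mean age (slope < 1).
#'
#' @param x A filtered [cohort()].
#' @return A [ba_estimates()] with method `"MLR"`.
#' @export
estimate_mlr <- function(x) {
  stopifnot(inherits(x, "cohort"))
  X <- marker_matrix(x)
  if (nrow(X) <= ncol(X) + 1L) stop("need n > J + 1 subjects for MLR")
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1L)
    stop("marker matrix is rank deficient (collinear markers)")
  fitted <- qr.fitted(qrX, x$ca_t0)
  ba_estimates("MLR", fitted, x$ca_t0)
}

#' Principal-component biological age
#'
#' First principal component of the z-scored markers, sign-aligned to
#' correlate positively with chronological age, then mapped to age units
#' so that BA has exactly the mean and SD of CA:
#' `BA = mean(CA) + PC1_z * SD(CA)` with `PC1_z` the unit-variance PC1
#' score.
#'
#' @param x A filtered [cohort()].
#' @return A [ba_estimates()] with method `"PCA"`.
#' @export
estimate_pca <- function(x) {
  stopifnot(inherits(x, "cohort"))
  X <- marker_matrix(x)
  if (ncol(X) < 2L) stop("PCA needs at least 2 markers")
  sds <- apply(X, 2, stats::sd)
  if (any(sds <= 0))
    stop("zero-variance marker(s): ",
         paste(colnames(X)[sds <= 0], collapse = ", "))
  Z <- scale(X)
  pc1 <- stats::prcomp(Z, center = FALSE, scale. = FALSE)$x[, 1]
  if (stats::cor(pc1, x$ca_t0) < 0) pc1 <- -pc1
  pc1z <- pc1 / stats::sd(pc1)
  ba <- mean(x$ca_t0) + pc1z * stats::sd(x$ca_t0)
  ba_estimates("PCA", ba, x$ca_t0)
}

#' Klemera-Doubal calibration
#'
#' Step one of the two-step estimator: a bivariate OLS regression of each
#' marker on chronological age, `x_j = q_j + k_j * CA + e_j`, retaining the
#' slope `k_j`, intercept `q_j`, residual SD `s_j` and correlation `r_j`.
#' Markers numerically uncorrelated with age are excluded from the
#' weighted sum with a warning. The SD of BA around CA, `s_BA`, defaults
#' to \eqn{s_{BA}^2 = \max(\epsilon,\; \overline{(BA_E - CA)^2} -
#' \frac{1-\bar r^2}{\bar r^2}\cdot\frac{(CA_{max}-CA_{min})^2}{12 J})}
#' with \eqn{\bar r} the mean absolute marker-age correlation; supply
#' `s_ba2` to override.
#'
#' @param x A filtered [cohort()].
#' @param s_ba2 Optional user-supplied value of `s_BA^2` (years^2).
#' @return An object of class `kd_calibration`.
#' @export
kd_calibrate <- function(x, s_ba2 = NULL) {
  stopifnot(inherits(x, "cohort"))
  X <- marker_matrix(x)
  ca <- x$ca_t0
  J <- ncol(X)
  q <- k <- s <- r <- numeric(J)
  for (j in seq_len(J)) {
    fit <- stats::lm.fit(cbind(1, ca), X[, j])
    q[j] <- fit$coefficients[1]
    k[j] <- fit$coefficients[2]
    s[j] <- sqrt(sum(fit$residuals^2) / (nrow(X) - 2))
    r[j] <- stats::cor(X[, j], ca)
  }
  names(q) <- names(k) <- names(s) <- names(r) <- colnames(X)
  ## a marker whose residual SD is numerically zero (an exact function of
  ## age) would get infinite weight: exclude it as degenerate
  usable <- abs(r) > sqrt(.Machine$double.eps) &
    s > 1e-7 * apply(X, 2, stats::sd)
  if (!all(usable))
    warning("marker(s) excluded from KD weighting (uncorrelated with age ",
            "or degenerate): ",
            paste(colnames(X)[!usable], collapse = ", "))
  if (!any(usable)) stop("no usable markers for KD calibration")

  ## provisional uncorrected BA to calibrate s_BA
  w_num <- sweep(X[, usable, drop = FALSE], 2, q[usable]) %*%
    (k[usable] / s[usable]^2)
  w_den <- sum((k[usable] / s[usable])^2)
  ba_e <- drop(w_num) / w_den
  if (is.null(s_ba2)) {
    rbar <- mean(abs(r[usable]))
    J_use <- sum(usable)
    s_ba2 <- max(1e-6,
                 mean((ba_e - ca)^2) -
                   ((1 - rbar^2) / rbar^2) *
                   (max(ca) - min(ca))^2 / (12 * J_use))
  }
  structure(list(q = q, k = k, s = s, r = r, usable = usable,
                 s_ba = sqrt(s_ba2),
                 age_range = range(ca)),
            class = "kd_calibration")
}

#' @export
print.kd_calibration <- function(x, ...) {
  cat(sprintf("<kd_calibration> %d markers (%d usable), s_BA = %.2f y, ages [%.1f, %.1f]\n",
              length(x$k), sum(x$usable), x$s_ba,
              x$age_range[1], x$age_range[2]))
  invisible(x)
}

#' Klemera-Doubal biological age
#'
#' Step two: combine the per-marker calibrations into an inverse-variance
#' weighted age. The uncorrected estimator is
#' \deqn{BA_E = \frac{\sum_j (x_j - q_j)\, k_j / s_j^2}
#'                   {\sum_j (k_j / s_j)^2},}
#' and the corrected (default) estimator shrinks toward chronological age
#' with weight \eqn{1/s_{BA}^2}:
#' \deqn{BA = \frac{\sum_j (x_j - q_j)\, k_j / s_j^2 + CA / s_{BA}^2}
#'                 {\sum_j (k_j / s_j)^2 + 1 / s_{BA}^2}.}
#'
#' @param x A filtered [cohort()].
#' @param cal A [kd_calibrate()] result.
#' @param corrected Return the CA-shrunk estimator (default) or the pure
#'   biomarker estimator `BA_E`.
#' @return A [ba_estimates()] with method `"KD"`; the uncorrected vector
#'   is attached as attribute `"ba_e"`.
#' @export
estimate_kd <- function(x, cal = kd_calibrate(x), corrected = TRUE) {
  stopifnot(inherits(x, "cohort"), inherits(cal, "kd_calibration"))
  X <- marker_matrix(x)
  u <- cal$usable
  if (!any(u)) stop("calibration has no usable markers")
  num <- unname(drop(sweep(X[, u, drop = FALSE], 2, cal$q[u]) %*%
                       (cal$k[u] / cal$s[u]^2)))
  den <- sum((cal$k[u] / cal$s[u])^2)
  ba_e <- num / den
  ba <- if (corrected)
    (num + x$ca_t0 / cal$s_ba^2) / (den + 1 / cal$s_ba^2)
  else ba_e
  out <- ba_estimates("KD", ba, x$ca_t0)
  attr(out, "ba_e") <- ba_e
  out
}
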