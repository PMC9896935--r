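#' Specify the one-factor measurement model
#'
#' The model treats biological age (BA) as a latent variable measured by
#' the biomarkers and structurally linked to chronological age:
#' \deqn{x_j = \nu_j + \lambda_j BA + \epsilon_j, \qquad
#'       BA = c + b\, g(CA) + \zeta,}
#' with \eqn{g} the identity (`form = "linear"`) or the natural log
#' (`form = "loglinear"`), \eqn{\epsilon_j \sim N(0, \theta_j)} and
#' \eqn{\zeta \sim N(0, \psi)}. Identification follows the
#' reference-indicator convention: the first marker's loading is fixed at 1
#' and its intercept at 0, so the latent factor carries that marker's
#' scale. Downstream BA estimates are invariant to this choice.
#'
#' @param markers Character vector of marker names (>= 3 for
#'   identification).
#' @param form `"linear"` or `"loglinear"`: whether CA or ln CA enters the
#'   structural regression.
#' @return An object of class `sem_spec`.
#' @export
sem_spec <- function(markers, form = c("linear", "loglinear")) {
  form <- match.arg(form)
  if (length(markers) < 3L)
    stop("a one-factor model needs at least 3 markers for identification")
  structure(list(markers = markers, form = form), class = "sem_spec")
}

## model-implied joint moments of (markers, g(CA)) given a parameter list
sem_implied <- function(par, mu_a, var_a) {
  J <- length(par$lambda)
  mu_ba <- par$c + par$b * mu_a
  v_ba <- par$b^2 * var_a + par$psi
  mu <- c(par$nu + par$lambda * mu_ba, mu_a)
  Sigma <- matrix(0, J + 1, J + 1)
  Sigma[seq_len(J), seq_len(J)] <-
    tcrossprod(par$lambda) * v_ba + diag(par$theta, J)
  Sigma[seq_len(J), J + 1] <- Sigma[J + 1, seq_len(J)] <-
    par$lambda * par$b * var_a
  Sigma[J + 1, J + 1] <- var_a
  list(mu = mu, Sigma = Sigma)
}

## free-parameter vector <-> structured list (variances on log scale)
sem_unpack <- function(v, J) {
  list(nu = unname(c(0, v[seq_len(J - 1)])),
       lambda = unname(c(1, v[(J - 1) + seq_len(J - 1)])),
       theta = unname(exp(v[2 * (J - 1) + seq_len(J)])),
       c = unname(v[3 * J - 1]), b = unname(v[3 * J]),
       psi = unname(exp(v[3 * J + 1])))
}

sem_pack <- function(par) {
  J <- length(par$lambda)
  c(par$nu[-1], par$lambda[-1], log(par$theta), par$c, par$b, log(par$psi))
}

## -2 * joint multivariate-normal log-likelihood from sufficient statistics
sem_m2ll <- function(v, J, ybar, S, mu_a, var_a, n) {
  par <- sem_unpack(v, J)
  imp <- sem_implied(par, mu_a, var_a)
  ch <- tryCatch(chol(imp$Sigma), error = function(e) NULL)
  if (is.null(ch)) return(1e12)
  logdet <- 2 * sum(log(diag(ch)))
  Sinv_d <- backsolve(ch, forwardsolve(t(ch), cbind(S, ybar - imp$mu)))
  tr <- sum(diag(Sinv_d[, seq_len(J + 1), drop = FALSE]))
  quad <- sum((ybar - imp$mu) * Sinv_d[, J + 2])
  val <- n * ((J + 1) * log(2 * pi) + logdet + tr + quad)
  if (!is.finite(val)) 1e12 else val
}

#' Fit the one-factor SEM by maximum likelihood
#'
#' Full-information maximum likelihood on the joint moments of the markers
#' and the exogenous regressor g(CA), assuming multivariate normality. The
#' exogenous block is saturated (its mean and variance fixed at the sample
#' moments), so the reported log-likelihood is the conditional likelihood
#' of the markers given g(CA); AIC/BIC for the linear and log-linear forms
#' are therefore comparable — both score the same marker data.
#'
#' Optimization is quasi-Newton from principal-axis starting values with
#' residual variances and the disturbance variance on the log scale; up to
#' five jittered restarts are attempted on non-convergence.
#'
#' @param x A filtered [cohort()].
#' @param spec A [sem_spec()]; defaults to all markers of `x`, linear form.
#' @return An object of class `sem_fit` with elements `nu`, `lambda`,
#'   `theta` (residual variances), `c`, `b` (structural intercept/slope on
#'   g(CA)), `psi` (disturbance variance), `loglik` (conditional),
#'   `npar`, `aic`, `bic`, `srmr`, `n`, `converged`.
#' @export
fit_sem <- function(x, spec = NULL) {
  stopifnot(inherits(x, "cohort"))
  if (is.null(spec)) spec <- sem_spec(marker_names(x))
  stopifnot(inherits(spec, "sem_spec"))
  miss <- setdiff(spec$markers, names(x))
  if (length(miss))
    stop("spec markers absent from cohort: ", paste(miss, collapse = ", "))
  X <- as.matrix(as.data.frame(x)[, spec$markers, drop = FALSE])
  if (anyNA(X) || anyNA(x$ca_t0))
    stop("cohort contains missing values; apply eligibility filters first")
  zv <- spec$markers[apply(X, 2, stats::var) <= 0]
  if (length(zv))
    stop("zero-variance marker(s): ", paste(zv, collapse = ", "))
  if (spec$form == "loglinear" && any(x$ca_t0 <= 0))
    stop("loglinear form requires strictly positive ages")
  a <- if (spec$form == "loglinear") log(x$ca_t0) else x$ca_t0

  n <- nrow(X)
  J <- ncol(X)
  Y <- cbind(X, a)
  ybar <- colMeans(Y)
  S <- crossprod(sweep(Y, 2, ybar)) / n      # n-denominator moments
  mu_a <- ybar[J + 1]
  var_a <- S[J + 1, J + 1]

  ## principal-axis starting values on the marker covariance block
  Sxx <- S[seq_len(J), seq_len(J)]
  e <- eigen(Sxx, symmetric = TRUE)
  l1 <- e$vectors[, 1] * sqrt(max(e$values[1], 1e-8))
  if (l1[1] < 0) l1 <- -l1
  lam0 <- l1 / l1[1]
  vba0 <- l1[1]^2
  th0 <- pmax(diag(Sxx) - lam0^2 * vba0, 0.05 * diag(Sxx))
  b0 <- S[1, J + 1] / var_a
  psi0 <- max(vba0 - b0^2 * var_a, 0.05 * vba0)
  c0 <- ybar[1] - b0 * mu_a
  mu_ba0 <- ybar[1]
  nu0 <- ybar[seq_len(J)] - lam0 * mu_ba0
  start <- sem_pack(list(nu = c(0, nu0[-1]), lambda = lam0, theta = th0,
                         c = c0, b = b0, psi = psi0))

  best <- NULL
  for (try in 0:5) {
    v0 <- if (try == 0) start else start * (1 + 0.1 * stats::rnorm(length(start)))
    opt <- tryCatch(
      stats::optim(v0, sem_m2ll, J = J, ybar = ybar, S = S, mu_a = mu_a,
                   var_a = var_a, n = n, method = "BFGS",
                   control = list(maxit = 2000, reltol = 1e-14)),
      error = function(e) NULL)
    if (!is.null(opt) && (is.null(best) || opt$value < best$value)) best <- opt
    if (!is.null(best) && best$convergence == 0) break
  }
  if (is.null(best))
    stop("SEM optimization failed: no run produced a finite likelihood")
  converged <- best$convergence == 0
  par <- sem_unpack(best$par, J)
  names(par$nu) <- names(par$lambda) <- names(par$theta) <- spec$markers

  ## conditional (markers | g(CA)) log-likelihood: joint minus saturated A
  m2ll_joint <- best$value
  m2ll_a <- n * (log(2 * pi) + log(var_a) + 1)
  loglik <- -(m2ll_joint - m2ll_a) / 2
  npar <- 3L * J + 1L
  imp <- sem_implied(par, mu_a, var_a)
  sdv <- sqrt(diag(S))
  resid_std <- (S - imp$Sigma) / tcrossprod(sdv)
  srmr <- sqrt(mean(resid_std[upper.tri(resid_std, diag = TRUE)]^2))

  structure(list(spec = spec, nu = par$nu, lambda = par$lambda,
                 theta = par$theta, c = par$c, b = par$b, psi = par$psi,
                 loglik = loglik, npar = npar,
                 aic = -2 * loglik + 2 * npar,
                 bic = -2 * loglik + npar * log(n),
                 srmr = srmr, n = n,
                 mu_a = mu_a, var_a = var_a,
                 converged = converged, m2ll_joint = m2ll_joint),
            class = "sem_fit")
}

#' @export
print.sem_fit <- function(x, ...) {
  cat(sprintf("<sem_fit> one-factor model, %s form, %d markers, n = %d\n",
              x$spec$form, length(x$lambda), x$n))
  cat(sprintf("  structural: BA = %.4g + %.4g * g(CA) + zeta, psi = %.4g\n",
              x$c, x$b, x$psi))
  cat("  loadings:", paste(sprintf("%.3f", x$lambda), collapse = " "), "\n")
  cat(sprintf("  loglik = %.2f, AIC = %.2f, BIC = %.2f, SRMR = %.4f%s\n",
              x$loglik, x$aic, x$bic, x$srmr,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

#' Factor scores from a fitted SEM
#'
#' Regression-method (expected a posteriori) scores: the conditional mean
#' of the latent factor given the markers and g(CA) under the fitted
#' Gaussian model, \eqn{FS_i = \mu_{BA} + \Sigma_{BA,y}\Sigma_{yy}^{-1}
#' (y_i - \mu_y)}. Scores are unitless up to the reference marker's scale
#' and serve only to rank subjects; every downstream BA estimate is
#' invariant to affine rescaling of the scores.
#'
#' @param fit A converged [fit_sem()].
#' @param x The cohort the scores are wanted for (markers must match the
#'   fit's marker set).
#' @return An object of class `factor_scores`: numeric vector of length
#'   `nrow(x)` with attribute `method`.
#' @export
factor_scores <- function(fit, x) {
  stopifnot(inherits(fit, "sem_fit"), inherits(x, "cohort"))
  if (!fit$converged) stop("SEM fit did not converge; no scores computed")
  miss <- setdiff(fit$spec$markers, names(x))
  if (length(miss))
    stop("cohort lacks marker(s) of the fit: ", paste(miss, collapse = ", "))
  X <- as.matrix(as.data.frame(x)[, fit$spec$markers, drop = FALSE])
  a <- if (fit$spec$form == "loglinear") log(x$ca_t0) else x$ca_t0
  J <- ncol(X)
  par <- list(nu = fit$nu, lambda = fit$lambda, theta = fit$theta,
              c = fit$c, b = fit$b, psi = fit$psi)
  imp <- sem_implied(par, fit$mu_a, fit$var_a)
  v_ba <- fit$b^2 * fit$var_a + fit$psi
  cov_ba_y <- c(fit$lambda * v_ba, fit$b * fit$var_a)
  w <- solve(imp$Sigma, cov_ba_y)
  mu_ba <- fit$c + fit$b * fit$mu_a
  fs <- drop(mu_ba + sweep(cbind(X, a), 2, imp$mu) %*% w)
  if (any(!is.finite(fs))) stop("non-finite factor scores")
  structure(fs, method = "regression", class = "factor_scores")
}

#' Fit statistics of a SEM fit
#'
#' @param fit A converged [fit_sem()].
#' @return List with `loglik`, `aic` (= -2l + 2p), `bic` (= -2l + p ln n)
#'   and `srmr` (standardized root mean square residual of the fitted vs
#'   observed covariance of markers and g(CA)).
#' @export
sem_fit_stats <- function(fit) {
  stopifnot(inherits(fit, "sem_fit"))
  if (!fit$converged) stop("SEM fit did not converge")
  list(loglik = fit$loglik, aic = fit$aic, bic = fit$bic, srmr = fit$srmr)
}
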