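#' Fit a Gompertz proportional-hazard model with right censoring
#'
#' Maximum likelihood for the hazard
#' \deqn{\mu_i(t) = k \exp(\beta\, CA_i + \beta t + x_i'\theta)}
#' where \eqn{t} is time since baseline, \eqn{CA_i} baseline age and
#' \eqn{x_i} optional fixed covariates (e.g. factor scores or the BA - CA
#' gap). By default the coefficient of baseline age is constrained to
#' equal the duration slope \eqn{\beta} — implemented structurally, one
#' parameter serving both roles — so \eqn{\beta} is the classical Gompertz
#' rate-of-aging. With `constrain_age_equals_duration = FALSE` baseline
#' age gets its own coefficient \eqn{\alpha}.
#'
#' The log-likelihood with right censoring is
#' \eqn{\ell = \sum_i d_i \ln \mu_i(t_i) - H_i(t_i)} with cumulative
#' hazard \eqn{H_i(t) = (k/\beta) e^{\beta CA_i + x_i'\theta}
#' (e^{\beta t} - 1)}. Optimization is quasi-Newton over
#' \eqn{(\ln k, \beta, \theta)} with the analytic gradient; standard
#' errors come from the observed information matrix, delta-method
#' back-transformed for `k`.
#'
#' @param x A filtered [cohort()] with at least one death.
#' @param covariates Named list of numeric per-subject vectors to enter
#'   the log-hazard linearly; empty for the null model.
#' @param constrain_age_equals_duration Share one coefficient between
#'   baseline age and duration (default TRUE, the headline models).
#' @return Object of class `gompertz_fit`: `k`, `beta`, `alpha` (baseline
#'   age coefficient; equals `beta` under the constraint), `coef` (named
#'   covariate effects), `se`, `ci` (95% Wald), `loglik`, `npar`, `aic`,
#'   `bic`, `n`, `events`, `vcov` (working scale, ln k first),
#'   `converged`.
#' @export
fit_gompertz <- function(x, covariates = list(),
                         constrain_age_equals_duration = TRUE) {
  stopifnot(inherits(x, "cohort"))
  ca <- x$ca_t0
  tt <- x$duration
  d <- x$dead
  n <- length(ca)
  if (sum(d) == 0) stop("no events: cannot fit a hazard model")
  if (length(covariates)) {
    stopifnot(!is.null(names(covariates)), all(nzchar(names(covariates))))
    Z <- do.call(cbind, lapply(covariates, as.numeric))
    if (nrow(Z) != n) stop("covariate length does not match cohort")
    if (any(!is.finite(Z))) stop("non-finite covariate values")
  } else Z <- matrix(0, n, 0)
  nz <- ncol(Z)
  con <- constrain_age_equals_duration

  ## parameter vector: (ln k, beta, [alpha], theta_1..theta_nz)
  idx_a <- if (con) integer(0) else 3L
  unpack <- function(p) {
    list(lk = p[1], beta = p[2],
         alpha = if (con) p[2] else p[3],
         theta = if (nz) p[(if (con) 2L else 3L) + seq_len(nz)] else numeric(0))
  }
  nll <- function(p) {
    q <- unpack(p)
    if (q$beta <= 0) return(1e12)
    lp <- if (nz) drop(Z %*% q$theta) else 0
    ll <- gompertz_loglik(exp(q$lk), q$beta, tt, d, ca,
                          alpha = q$alpha, lp = lp)
    if (!is.finite(ll)) 1e12 else -ll
  }
  ngr <- function(p) {
    q <- unpack(p)
    if (q$beta <= 0) return(rep(0, length(p)))
    eta <- q$alpha * ca + if (nz) drop(Z %*% q$theta) else 0
    base <- exp(q$lk + eta)
    H <- base * expm1(q$beta * tt) / q$beta
    r <- d - H
    g_lk <- sum(r)
    dH_dbeta_time <- base * tt * exp(q$beta * tt) / q$beta - H / q$beta
    g_beta <- sum(d * tt) - sum(dH_dbeta_time)
    if (con) g_beta <- g_beta + sum(ca * r)
    g <- c(g_lk, g_beta)
    if (!con) g <- c(g, sum(ca * r))
    if (nz) g <- c(g, drop(crossprod(Z, r)))
    -g
  }

  beta0 <- 0.08
  k0 <- sum(d) / sum(exp(beta0 * ca) * expm1(beta0 * tt) / beta0)
  p0 <- c(log(k0), beta0)
  if (!con) p0 <- c(p0, beta0)
  if (nz) p0 <- c(p0, rep(0, nz))

  opt <- stats::optim(p0, nll, ngr, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-14))
  ## Newton polish via the observed information
  hess <- stats::optimHess(opt$par, nll, ngr)
  step <- tryCatch(solve(hess, -ngr(opt$par)), error = function(e) NULL)
  if (!is.null(step) && all(is.finite(step))) {
    cand <- opt$par + step
    if (nll(cand) <= opt$value) {
      opt$par <- cand
      opt$value <- nll(cand)
      hess <- stats::optimHess(opt$par, nll, ngr)
    }
  }
  gn <- sqrt(sum(ngr(opt$par)^2))
  converged <- opt$convergence == 0 || gn < 1e-3
  if (!converged)
    stop(sprintf("Gompertz fit failed to converge (gradient norm %.3g)", gn))

  q <- unpack(opt$par)
  vcov <- tryCatch(solve(hess), error = function(e)
    matrix(NA_real_, length(opt$par), length(opt$par)))
  senames <- c("log_k", "beta", if (!con) "alpha",
               if (nz) names(covariates))
  dimnames(vcov) <- list(senames, senames)
  se_work <- unname(sqrt(pmax(diag(vcov), 0)))
  k <- exp(q$lk)
  est <- c(k = k, beta = q$beta,
           if (!con) c(alpha = q$alpha),
           if (nz) stats::setNames(q$theta, names(covariates)))
  se <- c(k = k * se_work[1], beta = se_work[2],
          if (!con) c(alpha = se_work[3]),
          if (nz) stats::setNames(se_work[(if (con) 2L else 3L) + seq_len(nz)],
                                  names(covariates)))
  zc <- stats::qnorm(0.975)
  ci <- cbind(lower = est - zc * se, upper = est + zc * se)
  ci["k", ] <- exp(q$lk + c(-1, 1) * zc * se_work[1])  # log-scale Wald for k

  loglik <- -opt$value
  npar <- length(opt$par)
  structure(list(k = k, beta = q$beta, alpha = q$alpha,
                 coef = if (nz) stats::setNames(q$theta, names(covariates))
                        else stats::setNames(numeric(0), character(0)),
                 estimates = est, se = se, ci = ci,
                 loglik = loglik, npar = npar,
                 aic = -2 * loglik + 2 * npar,
                 bic = -2 * loglik + npar * log(n),
                 n = n, events = sum(d),
                 constrained = con, vcov = vcov,
                 gradient_norm = gn, converged = converged),
            class = "gompertz_fit")
}

#' @export
print.gompertz_fit <- function(x, ...) {
  cat(sprintf("<gompertz_fit> n = %d, events = %d%s\n", x$n, x$events,
              if (x$constrained) ", baseline age coef = duration coef" else ""))
  cat(sprintf("  k = %.3g (95%% CI %.3g, %.3g)\n", x$k,
              x$ci["k", 1], x$ci["k", 2]))
  cat(sprintf("  beta = %.4f (doubling time %.1f y)\n", x$beta,
              doubling_time(x$beta)))
  for (nm in names(x$coef))
    cat(sprintf("  %s = %.4f (SE %.4f)\n", nm, x$coef[[nm]], x$se[[nm]]))
  cat(sprintf("  loglik = %.1f, AIC = %.1f, BIC = %.1f\n",
              x$loglik, x$aic, x$bic))
  invisible(x)
}

#' Right-censored Gompertz log-likelihood
#'
#' Evaluates \eqn{\ell = \sum_i d_i \ln \mu_i(t_i) - H_i(t_i)} for the
#' hazard \eqn{\mu_i(t) = k \exp(\alpha\, CA_i + lp_i + \beta t)} with
#' cumulative hazard \eqn{H_i(t) = (k/\beta) e^{\alpha CA_i + lp_i}
#' (e^{\beta t} - 1)}. Used internally by [fit_gompertz()] and exposed so
#' the likelihood can be inspected at arbitrary parameter values.
#'
#' @param k Hazard level (> 0).
#' @param beta Duration slope (> 0).
#' @param time Follow-up durations (years).
#' @param dead 0/1 event indicators.
#' @param age Baseline ages (years); use 0 to drop the age term.
#' @param alpha Baseline-age coefficient; defaults to `beta` (the
#'   constrained model).
#' @param lp Additional per-subject linear predictor (covariate effects).
#' @return The log-likelihood (scalar).
#' @export
gompertz_loglik <- function(k, beta, time, dead, age, alpha = beta, lp = 0) {
  stopifnot(k > 0, beta > 0)
  eta <- alpha * age + lp
  H <- (k / beta) * exp(eta) * expm1(beta * time)
  sum(dead * (log(k) + eta + beta * time)) - sum(H)
}

#' Mortality-rate doubling time
#'
#' Time for the Gompertz hazard to double: `ln(2) / beta`. Lengthening of
#' the doubling time when factor scores enter the hazard quantifies how
#' much apparent age-acceleration the biomarkers explain.
#'
#' @param beta Gompertz slope, per year (> 0).
#' @return Doubling time in years.
#' @export
doubling_time <- function(beta) {
  if (any(beta <= 0)) stop("doubling time requires beta > 0")
  log(2) / beta
}

#' Hazard ratio for a log-hazard coefficient
#'
#' @param coef Coefficient on the log-hazard scale.
#' @return `exp(coef)`, the multiplicative effect on the mortality rate
#'   per unit of the covariate.
#' @export
hazard_ratio <- function(coef) {
  if (any(!is.finite(coef))) stop("coef must be finite")
  exp(coef)
}

#' Information criteria of a hazard fit
#'
#' @param fit A [fit_gompertz()] result.
#' @return Named vector `c(aic, bic)` recomputed from the stored
#'   log-likelihood and parameter count.
#' @export
information_criteria <- function(fit) {
  stopifnot(inherits(fit, "gompertz_fit"))
  c(aic = -2 * fit$loglik + 2 * fit$npar,
    bic = -2 * fit$loglik + fit$npar * log(fit$n))
}
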