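#' Outcome-free biological age
#'
#' Second stage of the outcome-free estimator: regress observed
#' chronological age (linear form) or ln CA (log-linear form) on the
#' factor scores by OLS and take the fitted values — back-transformed by
#' `exp` in the log-linear case, with no retransformation correction — as
#' biological age. The calibration carries Wald tests of the hypotheses
#' under which the SEM estimator would collapse to the restricted
#' functional forms of older methods: intercept 0 and slope 1 (linear), or
#' 1 and 1 (log-linear).
#'
#' @param fs A [factor_scores()] vector.
#' @param x The cohort.
#' @param form `"linear"` (CA on FS) or `"loglinear"` (ln CA on FS).
#' @return List with `estimates` (a [ba_estimates()], method
#'   `"OF-linear"` or `"OF-nonlinear"`) and `calibration` (class
#'   `of_calibration`: `c0`, `c1`, their SEs, Wald z and p-values against
#'   the stated nulls, `form`).
#' @export
estimate_of <- function(fs, x, form = c("linear", "loglinear")) {
  form <- match.arg(form)
  stopifnot(inherits(x, "cohort"))
  fs <- as.numeric(fs)
  if (length(fs) != nrow(x)) stop("factor-score/cohort length mismatch")
  if (any(!is.finite(fs))) stop("non-finite factor scores")
  if (stats::sd(fs) == 0) stop("constant factor scores: no calibration possible")
  if (form == "loglinear" && any(x$ca_t0 <= 0))
    stop("loglinear form requires strictly positive ages")
  y <- if (form == "linear") x$ca_t0 else log(x$ca_t0)
  fit <- stats::lm(y ~ fs)
  cf <- summary(fit)$coefficients
  null_vals <- if (form == "linear") c(0, 1) else c(1, 1)
  z <- (cf[, 1] - null_vals) / cf[, 2]
  cal <- structure(list(c0 = unname(cf[1, 1]), c1 = unname(cf[2, 1]),
                        se = unname(cf[, 2]),
                        null = null_vals, wald_z = unname(z),
                        p = unname(2 * stats::pnorm(-abs(z))),
                        form = form),
                   class = "of_calibration")
  ba <- if (form == "linear") stats::fitted(fit) else exp(stats::fitted(fit))
  method <- if (form == "linear") "OF-linear" else "OF-nonlinear"
  list(estimates = ba_estimates(method, ba, x$ca_t0), calibration = cal)
}

#' @export
print.of_calibration <- function(x, ...) {
  cat(sprintf("<of_calibration> %s: BA intercept %.3f (SE %.3f), slope %.3f (SE %.3f)\n",
              x$form, x$c0, x$se[1], x$c1, x$se[2]))
  cat(sprintf("  H0 (c0, c1) = (%g, %g): z = (%.2f, %.2f), p = (%.3g, %.3g)\n",
              x$null[1], x$null[2], x$wald_z[1], x$wald_z[2],
              x$p[1], x$p[2]))
  invisible(x)
}

#' Outcome-dependent biological age
#'
#' Anchors biological age on mortality: BA is the age at which the null
#' Gompertz hazard equals the augmented hazard (with factor scores)
#' evaluated at the subject's actual age and score. Solving
#' \deqn{k_n e^{\beta_n \widehat{CA}} = k_a e^{\beta_a CA + \gamma FS}}
#' gives the closed form
#' \deqn{\widehat{CA} = \frac{\ln(k_a / k_n) + \beta_a CA + \gamma FS}
#'                           {\beta_n}.}
#' When the factor-score effect is zero and the null and augmented
#' parameters coincide, BA is identical to CA for every subject; a
#' positive \eqn{\gamma} with scores rising in age produces a BA-on-CA
#' slope above 1 — accelerated aging.
#'
#' @param fs A [factor_scores()] vector.
#' @param x The cohort.
#' @param null_fit Null-model [fit_gompertz()] (baseline age only,
#'   constrained).
#' @param aug_fit Augmented [fit_gompertz()] with the factor scores as a
#'   covariate named `"fs"` (or the single covariate present).
#' @param form Label only: `"linear"` or `"loglinear"`, tagging which SEM
#'   the scores came from.
#' @return A [ba_estimates()] with method `"OD-linear"` or
#'   `"OD-nonlinear"`.
#' @export
estimate_od <- function(fs, x, null_fit, aug_fit,
                        form = c("linear", "loglinear")) {
  form <- match.arg(form)
  stopifnot(inherits(x, "cohort"), inherits(null_fit, "gompertz_fit"),
            inherits(aug_fit, "gompertz_fit"))
  fs <- as.numeric(fs)
  if (length(fs) != nrow(x)) stop("factor-score/cohort length mismatch")
  if (any(!is.finite(fs))) stop("non-finite factor scores")
  if (null_fit$beta <= 0) stop("null Gompertz slope must be > 0")
  gamma <- if ("fs" %in% names(aug_fit$coef)) aug_fit$coef[["fs"]]
           else if (length(aug_fit$coef) == 1L) aug_fit$coef[[1L]]
           else stop("augmented fit must carry the factor-score coefficient")
  ## grouped so that identical null/augmented fits with gamma = 0 return
  ## CA bit-exactly (the ratio alpha/beta_n is then exactly 1)
  ba <- (log(aug_fit$k) - log(null_fit$k) + gamma * fs) / null_fit$beta +
    (aug_fit$alpha / null_fit$beta) * x$ca_t0
  method <- if (form == "linear") "OD-linear" else "OD-nonlinear"
  ba_estimates(method, ba, x$ca_t0)
}
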