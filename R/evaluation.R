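#' Remaining life expectancy under a Gompertz hazard
#'
#' Integrates the survival function implied by a fitted hazard from a
#' reference age, for a hypothetical subject whose BA - CA gap is `delta`:
#' \deqn{E = \int_0^{\omega} \exp\!\big(-(k/\beta)\,
#'   e^{\beta\,age + \phi\,delta}\,(e^{\beta t} - 1)\big)\,dt}
#' with \eqn{\phi} the fitted gap coefficient and the upper limit
#' \eqn{\omega = 120 - age}. Adaptive quadrature at relative tolerance
#' 1e-8.
#'
#' @param fit A [fit_gompertz()] result; its first (or `"delta"`-named)
#'   covariate coefficient is taken as \eqn{\phi}. A null fit (no
#'   covariates) implies \eqn{\phi = 0}.
#' @param age Reference age in years (e.g. 65).
#' @param delta BA - CA scenario in years.
#' @return Life expectancy in years.
#' @export
life_expectancy <- function(fit, age = 65, delta = 0) {
  stopifnot(inherits(fit, "gompertz_fit"))
  if (!is.finite(fit$k) || fit$k <= 0 || fit$beta <= 0)
    stop("fit must have k > 0 and beta > 0")
  phi <- if (!length(fit$coef)) 0
         else if ("delta" %in% names(fit$coef)) fit$coef[["delta"]]
         else fit$coef[[1L]]
  lev <- (fit$k / fit$beta) * exp(fit$alpha * age + phi * delta)
  surv <- function(t) exp(-lev * expm1(fit$beta * t))
  stats::integrate(surv, 0, 120 - age, rel.tol = 1e-8,
                   subdivisions = 500L)$value
}

#' Life-expectancy differences across BA - CA scenarios
#'
#' Evaluates E(age) on a grid of BA - CA gaps and reports the difference
#' against the `delta = 0` reference — the scenario analysis behind the
#' four-quadrant picture: biologically older subjects (positive gap) lose
#' remaining life expectancy, biologically younger ones gain it, with
#' steeper gap coefficients producing steeper losses.
#'
#' @param fit A [fit_gompertz()] with a gap coefficient (see
#'   [life_expectancy()]).
#' @param age Reference age in years.
#' @param delta_grid Gap scenarios in years, default -5..+5.
#' @return Data frame with columns `age`, `delta`, `e` (years) and
#'   `e_diff` (years, vs `delta = 0`; exactly 0 at `delta = 0`).
#' @export
e65_delta_curve <- function(fit, age = 65, delta_grid = seq(-5, 5, by = 1)) {
  stopifnot(all(is.finite(delta_grid)))
  e0 <- life_expectancy(fit, age, 0)
  e <- vapply(delta_grid, function(d)
    if (d == 0) e0 else life_expectancy(fit, age, d), numeric(1))
  data.frame(age = age, delta = delta_grid, e = e, e_diff = e - e0)
}

#' Full and partial area under the ROC curve
#'
#' Full AUC by the midrank (Mann-Whitney) statistic; partial AUC as the
#' area of the ROC curve over the false-positive-rate band implied by the
#' specificity band `(lo, hi)` — FPR in `[1 - hi, 1 - lo]` — normalized by
#' band width so a perfect classifier scores 1 on any band. The raw
#' (unnormalized) area is attached as attribute `"raw_area"`. Tied scores
#' are handled by midranks (diagonal ROC segments).
#'
#' @param scores Numeric risk scores, higher = more likely positive.
#' @param labels 0/1 outcome labels; both classes must be present.
#' @param specificity_band `c(lo, hi)` with `0 <= lo < hi <= 1`; the
#'   default `c(0, 1)` gives the full AUC.
#' @return The (normalized) AUC.
#' @export
roc_auc <- function(scores, labels, specificity_band = c(0, 1)) {
  stopifnot(length(scores) == length(labels),
            all(labels %in% c(0, 1)))
  lo <- specificity_band[1]; hi <- specificity_band[2]
  stopifnot(0 <= lo, lo < hi, hi <= 1)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both outcome classes must be present")

  if (lo == 0 && hi == 1) {
    r <- rank(scores)                      # midranks: ties -> 1/2 credit
    auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    attr(auc, "raw_area") <- auc
    return(auc)
  }

  ## ROC step curve: thresholds descending; ties grouped
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last <- !duplicated(grp, fromLast = TRUE)
  fpr <- c(0, fp[last] / n0)
  tpr <- c(0, tp[last] / n1)

  band <- c(1 - hi, 1 - lo)                # FPR window
  ## exact area of the empirical ROC polyline clipped to the band:
  ## vertical segments contribute nothing, tie diagonals integrate as
  ## trapezoids (midrank convention)
  raw <- 0
  for (i in seq_len(length(fpr) - 1L)) {
    x1 <- fpr[i]; x2 <- fpr[i + 1L]
    if (x2 <= band[1] || x1 >= band[2] || x2 == x1) next
    a <- max(x1, band[1]); b <- min(x2, band[2])
    t_a <- tpr[i] + (tpr[i + 1L] - tpr[i]) * (a - x1) / (x2 - x1)
    t_b <- tpr[i] + (tpr[i + 1L] - tpr[i]) * (b - x1) / (x2 - x1)
    raw <- raw + (b - a) * (t_a + t_b) / 2
  }
  auc <- raw / (band[2] - band[1])
  attr(auc, "raw_area") <- raw
  auc
}

#' Mortality risk score at a fixed horizon
#'
#' Model-predicted cumulative hazard at `horizon` years of follow-up for
#' each subject, for use as the ROC risk score. Subjects are labelled 1
#' if they died (of a non-excluded cause) by the horizon and 0 if they
#' were under observation at the horizon; subjects censored before the
#' horizon carry label `NA` and should be dropped from ROC evaluation.
#'
#' @param fit A [fit_gompertz()].
#' @param x The cohort.
#' @param covariates Named list of the same covariate vectors the fit was
#'   given (values at baseline).
#' @param horizon Follow-up horizon in years; defaults to the largest
#'   observed duration.
#' @return Data frame with `score` (cumulative hazard at the horizon) and
#'   `label`.
#' @export
mortality_risk_score <- function(fit, x, covariates = list(),
                                 horizon = max(x$duration)) {
  stopifnot(inherits(fit, "gompertz_fit"), inherits(x, "cohort"))
  lp <- if (length(covariates))
    drop(do.call(cbind, lapply(covariates, as.numeric)) %*%
           unname(fit$coef[names(covariates)]))
  else 0
  score <- (fit$k / fit$beta) * exp(fit$alpha * x$ca_t0 + lp) *
    expm1(fit$beta * horizon)
  label <- ifelse(x$dead == 1 & x$duration <= horizon, 1,
                  ifelse(x$duration >= horizon, 0, NA))
  data.frame(score = score, label = label)
}

#' Regression of biological age on chronological age
#'
#' The hypothesis battery on how an estimator relates BA to CA: OLS of BA
#' on CA with Wald tests of intercept = 0 and slope = 1, plus the
#' companion regression of the gap (BA - CA) on CA. Slopes below 1
#' (MLR/PCA/OF) compress biological aging relative to calendar aging;
#' only an outcome-anchored estimator can push the slope above 1.
#'
#' @param ba A [ba_estimates()].
#' @param x The cohort.
#' @return List with `slope`, `intercept`, their SEs, `wald` (z and p for
#'   intercept = 0 and slope = 1), `r_squared`, and `delta_fit` (lm of
#'   delta on CA).
#' @export
ba_ca_regression <- function(ba, x) {
  stopifnot(inherits(ba, "ba_estimates"), inherits(x, "cohort"))
  if (length(ba$ba) != nrow(x)) stop("estimate/cohort length mismatch")
  if (nrow(x) <= 2L) stop("need more than 2 subjects")
  ca <- x$ca_t0
  fit <- stats::lm(ba$ba ~ ca)
  cf <- summary(fit)$coefficients
  z <- (cf[, 1] - c(0, 1)) / cf[, 2]
  list(method = ba$method,
       intercept = unname(cf[1, 1]), slope = unname(cf[2, 1]),
       se = unname(cf[, 2]),
       wald = data.frame(null = c("intercept=0", "slope=1"),
                         z = unname(z),
                         p = unname(2 * stats::pnorm(-abs(z)))),
       r_squared = summary(fit)$r.squared,
       delta_fit = stats::lm(ba$delta ~ ca))
}

#' Disparity regression of the BA - CA gap
#'
#' Linear model for the gap as a function of age and categorical
#' covariates (sex, race/ethnicity, education), each with a stated
#' reference level, reporting the coefficient table together with
#' adjusted R-squared, AIC and BIC. Positive group coefficients mean the
#' group is biologically older at a given calendar age.
#'
#' @param ba A [ba_estimates()] (or list of them, one column per method).
#' @param x The cohort; must carry the covariates.
#' @param covariates Named list mapping covariate column -> reference
#'   level.
#' @return For a single estimate: list with `coefficients` (table),
#'   `adj_r_squared`, `aic`, `bic`, `n`, `method`. For a list of
#'   estimates: data frame with one coefficient column per method.
#' @export
disparity_regression <- function(ba, x,
                                 covariates = list(sex = "male",
                                                   race = "nh_white",
                                                   education = "less_hs")) {
  stopifnot(inherits(x, "cohort"))
  if (inherits(ba, "ba_estimates")) {
    df <- data.frame(delta = ba$delta, ca = x$ca_t0)
    for (cv in names(covariates)) {
      if (is.null(x[[cv]])) stop("cohort lacks covariate: ", cv)
      lev <- unique(x[[cv]])
      if (!covariates[[cv]] %in% lev)
        stop(sprintf("reference level '%s' absent from '%s' (levels: %s)",
                     covariates[[cv]], cv, paste(lev, collapse = ", ")))
      df[[cv]] <- stats::relevel(factor(x[[cv]]), ref = covariates[[cv]])
    }
    fml <- stats::as.formula(paste("delta ~ ca +",
                                   paste(names(covariates), collapse = " + ")))
    fit <- stats::lm(fml, data = df)
    sm <- summary(fit)
    return(list(method = ba$method,
                coefficients = stats::coef(sm),
                adj_r_squared = sm$adj.r.squared,
                aic = stats::AIC(fit), bic = stats::BIC(fit),
                n = nrow(df), fit = fit))
  }
  ## list of estimates -> one column per method, rows aligned on terms
  res <- lapply(ba, disparity_regression, x = x, covariates = covariates)
  terms <- rownames(res[[1]]$coefficients)
  out <- data.frame(term = terms)
  for (r in res) out[[r$method]] <- r$coefficients[terms, 1]
  extra <- data.frame(term = c("adj_r_squared", "aic", "bic", "n"))
  for (r in res)
    extra[[r$method]] <- c(r$adj_r_squared, r$aic, r$bic, r$n)
  rbind(out, extra)
}
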