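#' Generating truth for a synthetic cohort
#'
#' Parameters of the data-generating process the estimators assume: a
#' single latent deterioration factor linearly linked to chronological age,
#' biomarkers loading on that factor with Gaussian noise, and right-censored
#' Gompertz mortality whose log-hazard is linear in baseline age, time under
#' observation, and the standardized latent factor.
#'
#' The default fixture has n = 5,000 subjects aged 30-75, nine markers with
#' loadings (1.0, 0.9, 0.8, 0.7, 0.6, 0.5, 0.4, -0.6, -0.8) — the two
#' negative loadings mirror markers such as forced expiratory volume and
#' albumin, where higher values mean better physiological state — unit
#' residual SDs, a structural slope of 0.05/y with disturbance SD chosen so
#' age explains about half the latent variance, hazard level 1e-4/y, slope
#' 0.09/y, latent effect 1.5 per SD, and censoring at 25 years of follow-up.
#'
#' @param n Number of subjects (>= 2).
#' @param age_range Baseline-age range in years, `c(min, max)`.
#' @param struct_intercept,struct_slope Intercept and slope linking age to
#'   the latent factor.
#' @param psi Disturbance SD of the latent factor (>= 0).
#' @param loadings Vector of marker loadings (sign encodes orientation).
#' @param marker_intercepts Marker intercepts, recycled to the loadings.
#' @param residual_sds Marker residual SDs (> 0), recycled.
#' @param k Gompertz hazard level, per year (> 0).
#' @param beta Gompertz slope, per year (> 0).
#' @param gamma Log-hazard effect per SD of the latent factor.
#' @param censor_time Administrative censoring time, years (> 0).
#' @param excluded_cause_frac Fraction of deaths flagged as due to excluded
#'   causes (HIV/violence/accidents) in the raw file, before filtering.
#' @param covariate_probs Named list of probability vectors for the
#'   categorical covariates generated alongside (sex, race/ethnicity,
#'   education).
#' @param latent_group_shift Named numeric vector: additive shift of the
#'   latent factor (in latent units) for subjects in the named covariate
#'   level, e.g. `c(nh_black = 0.5)`; empty for none.
#' @param seed Integer seed governing every draw.
#' @return An object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(n = 5000L,
                            age_range = c(30, 75),
                            struct_intercept = 0,
                            struct_slope = 0.05,
                            psi = 0.05 * sqrt(45^2 / 12),
                            loadings = c(1, 0.9, 0.8, 0.7, 0.6, 0.5, 0.4,
                                         -0.6, -0.8),
                            marker_intercepts = seq(5, by = 5,
                                                    length.out = length(loadings)),
                            residual_sds = rep(1, length(loadings)),
                            k = 1e-4, beta = 0.09, gamma = 1.5,
                            censor_time = 25,
                            excluded_cause_frac = 0,
                            covariate_probs = list(
                              sex = c(female = 0.52, male = 0.48),
                              race = c(nh_white = 0.55, nh_black = 0.25,
                                       mex_ame = 0.20),
                              education = c(less_hs = 0.35, hs = 0.40,
                                            coll = 0.25)),
                            latent_group_shift = numeric(0),
                            seed = 20220726L) {
  marker_intercepts <- rep_len(marker_intercepts, length(loadings))
  residual_sds <- rep_len(residual_sds, length(loadings))
  truth <- structure(list(n = as.integer(n), age_range = age_range,
                          struct_intercept = struct_intercept,
                          struct_slope = struct_slope, psi = psi,
                          loadings = loadings,
                          marker_intercepts = marker_intercepts,
                          residual_sds = residual_sds,
                          k = k, beta = beta, gamma = gamma,
                          censor_time = censor_time,
                          excluded_cause_frac = excluded_cause_frac,
                          covariate_probs = covariate_probs,
                          latent_group_shift = latent_group_shift,
                          seed = as.integer(seed)),
                     class = "synthetic_truth")
  validate_truth(truth)
  truth
}

validate_truth <- function(truth) {
  with(truth, {
    if (n < 2L) stop("n must be >= 2")
    if (!(length(age_range) == 2L && age_range[1] < age_range[2]))
      stop("age_range must be an increasing pair of years")
    if (beta <= 0) stop("Gompertz slope beta must be > 0")
    if (k <= 0) stop("Gompertz level k must be > 0")
    if (psi < 0) stop("latent disturbance SD psi must be >= 0")
    if (any(residual_sds <= 0)) stop("residual SDs must be > 0")
    if (censor_time <= 0) stop("censor_time must be > 0")
    if (excluded_cause_frac < 0 || excluded_cause_frac > 1)
      stop("excluded_cause_frac must lie in [0, 1]")
  })
  invisible(truth)
}

#' Draw a Gompertz event time by inverse-CDF
#'
#' For hazard \eqn{\mu(t) = k_{eff} e^{\beta t}} the survival function is
#' \eqn{S(t) = \exp(-(k_{eff}/\beta)(e^{\beta t} - 1))}; inverting at
#' survival probability `u` gives
#' \eqn{T = (1/\beta)\,\ln(1 - (\beta/k_{eff}) \ln u)}.
#'
#' @param k_eff Effective hazard level at t = 0 (per year, > 0); for a
#'   subject aged `a` with linear predictor `lp`, `k_eff = k*exp(beta*a + lp)`.
#' @param beta Gompertz slope (per year, > 0).
#' @param u Uniform(0,1) survival draw, strictly inside (0, 1).
#' @return Event time in years; satisfies `S(T) = u` exactly.
#' @export
sample_gompertz_time <- function(k_eff, beta, u) {
  if (any(k_eff <= 0)) stop("k_eff must be > 0")
  if (any(beta <= 0)) stop("beta must be > 0")
  if (any(u <= 0 | u >= 1)) stop("u must lie strictly inside (0, 1)")
  log1p(-(beta / k_eff) * log(u)) / beta
}

#' Simulate a cohort with known truth
#'
#' Generates baseline ages uniform on the age range, a latent deterioration
#' factor linear in age with Gaussian disturbance, biomarkers as noisy
#' linear functions of the latent factor, categorical covariates, and
#' right-censored Gompertz survival whose log-hazard is linear in baseline
#' age, elapsed time, and the standardized latent factor (so `gamma` is per
#' SD of latent deterioration, matching the unitless character of factor
#' scores). The same seed yields a bit-identical cohort.
#'
#' @param truth A [synthetic_truth()].
#' @return A list with components `cohort` (a [cohort()]) and `latent`
#'   (the true latent vector, for recovery tests).
#' @export
simulate_cohort <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  validate_truth(truth)
  set.seed(truth$seed)
  n <- truth$n
  J <- length(truth$loadings)

  ca <- stats::runif(n, truth$age_range[1], truth$age_range[2])
  covs <- lapply(truth$covariate_probs, function(p)
    sample(names(p), n, replace = TRUE, prob = p))

  latent <- truth$struct_intercept + truth$struct_slope * ca +
    stats::rnorm(n, 0, truth$psi)
  if (length(truth$latent_group_shift)) {
    for (lvl in names(truth$latent_group_shift)) {
      hit <- Reduce(`|`, lapply(covs, function(v) v == lvl))
      latent[hit] <- latent[hit] + truth$latent_group_shift[[lvl]]
    }
  }

  x <- matrix(0, n, J)
  for (j in seq_len(J))
    x[, j] <- truth$marker_intercepts[j] + truth$loadings[j] * latent +
      stats::rnorm(n, 0, truth$residual_sds[j])
  colnames(x) <- sprintf("marker%02d", seq_len(J))

  z <- (latent - mean(latent)) / stats::sd(latent)
  k_eff <- truth$k * exp(truth$beta * ca + truth$gamma * z)
  u <- stats::runif(n)
  tt <- sample_gompertz_time(k_eff, truth$beta, u)
  dead <- as.integer(tt <= truth$censor_time)
  duration <- pmin(tt, truth$censor_time)

  excluded <- integer(n)
  if (truth$excluded_cause_frac > 0) {
    is_death <- which(dead == 1L)
    excluded[is_death] <-
      stats::rbinom(length(is_death), 1L, truth$excluded_cause_frac)
  }

  df <- data.frame(subject_id = seq_len(n), ca_t0 = ca, duration = duration,
                   dead = dead, excluded_cause = excluded,
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(x), as.data.frame(covs,
                                                  stringsAsFactors = FALSE))
  orientation <- ifelse(truth$loadings >= 0, 1, -1)
  names(orientation) <- colnames(x)
  ch <- cohort(df, markers = colnames(x),
               covariates = names(truth$covariate_probs),
               orientation = orientation)
  list(cohort = ch, latent = latent)
}
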