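# Shared fixtures, memoised so expensive simulations run once per session.

.fixture_env <- new.env(parent = emptyenv())

# Default synthetic cohort (the study conditions), filtered, plus truth
# and true latent. Built lazily; seed fixed.
default_fixture <- function() {
  if (is.null(.fixture_env$default)) {
    truth <- synthetic_truth(seed = 20220726L)
    sim <- simulate_cohort(truth)
    ch <- apply_eligibility_filters(sim$cohort)
    .fixture_env$default <- list(truth = truth, cohort = ch,
                                 latent = sim$latent)
  }
  .fixture_env$default
}

# SEM fit + factor scores on the default fixture.
default_sem <- function() {
  if (is.null(.fixture_env$sem)) {
    fx <- default_fixture()
    fit <- fit_sem(fx$cohort)
    .fixture_env$sem <- list(fit = fit,
                             fs = factor_scores(fit, fx$cohort))
  }
  .fixture_env$sem
}

# Small hand-sized cohort from explicit vectors.
toy_cohort <- function(ca, markers, duration = rep(1, length(ca)),
                       dead = rep(0, length(ca)),
                       excluded_cause = rep(0, length(ca))) {
  df <- data.frame(ca_t0 = ca, duration = duration, dead = dead,
                   excluded_cause = excluded_cause)
  df <- cbind(df, as.data.frame(markers))
  cohort(df, markers = colnames(as.data.frame(markers)))
}

# Minimal gompertz_fit-shaped object for evaluation tests that need fixed
# parameters rather than a fitted model.
fake_gfit <- function(k, beta, phi = NULL, alpha = beta) {
  structure(list(k = k, beta = beta, alpha = alpha,
                 coef = if (is.null(phi)) stats::setNames(numeric(0), character(0))
                        else c(delta = phi),
                 loglik = NA_real_, npar = 2L, n = 1L, events = 1L,
                 constrained = TRUE, converged = TRUE),
            class = "gompertz_fit")
}
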