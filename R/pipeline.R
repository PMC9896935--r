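#' Run the full biological-age workflow
#'
#' Orchestrates the complete analysis: simulate or read a cohort, apply
#' the eligibility filters (ages 30-75, complete cases, excluded-cause
#' deaths censored), fit the SEM(s), compute BA by every requested method,
#' fit the null / factor-score-augmented / gap hazard models, and run the
#' downstream evaluations. All outputs are written to `out_dir` as plain
#' CSV/JSON plus a manifest; the same config and seed reproduce the bundle
#' byte for byte.
#'
#' @param config A list with elements:
#'   \describe{
#'     \item{simulate}{list of [synthetic_truth()] arguments, or `NULL`
#'       when reading a file;}
#'     \item{input, columns}{file path and [column_config()] argument
#'       list, used when `simulate` is `NULL`;}
#'     \item{methods}{character subset of `c("mlr","pca","kd","of","od")`;}
#'     \item{forms}{SEM forms for of/od, subset of
#'       `c("linear","loglinear")`;}
#'     \item{age_min, age_max}{eligibility bounds (default 30, 75);}
#'     \item{out_dir}{output directory;}
#'     \item{seed}{integer seed (required when simulating).}
#'   }
#' @return Invisibly, a list with the cohort, fits, estimates and
#'   evaluation tables.
#' @export
run_pipeline <- function(config) {
  methods <- tolower(config$methods %||% c("mlr", "pca", "kd", "of", "od"))
  if (!length(methods)) stop("config must request at least one method")
  bad <- setdiff(methods, c("mlr", "pca", "kd", "of", "od"))
  if (length(bad)) stop("unknown method(s): ", paste(bad, collapse = ", "))
  forms <- config$forms %||% "linear"
  out_dir <- config$out_dir %||% stop("config$out_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  log_stage <- function(fmt, ...) {
    message(sprintf("[bioage %s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...)))
  }

  if (!is.null(config$simulate)) {
    if (is.null(config$seed)) stop("simulation requires config$seed")
    truth <- do.call(synthetic_truth,
                     c(config$simulate, list(seed = config$seed)))
    log_stage("simulating cohort (n = %d)", truth$n)
    sim <- simulate_cohort(truth)
    raw <- sim$cohort
    jsonlite::write_json(truth[setdiff(names(truth), "covariate_probs")],
                         file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  } else {
    if (is.null(config$input)) stop("config needs either $simulate or $input")
    log_stage("reading %s", config$input)
    raw <- read_cohort(config$input, do.call(column_config, config$columns))
  }

  log_stage("applying eligibility filters")
  ch <- apply_eligibility_filters(raw, config$age_min %||% 30,
                                  config$age_max %||% 75)
  rep <- attr(ch, "filter_report")
  utils::capture.output(print(rep),
                        file = file.path(out_dir, "filter_report.txt"))
  write_cohort(ch, file.path(out_dir, "cohort.csv"))

  estimates <- list()
  sem_fits <- list()
  hazard_fits <- list()

  if ("mlr" %in% methods) estimates$MLR <- estimate_mlr(ch)
  if ("pca" %in% methods) estimates$PCA <- estimate_pca(ch)
  if ("kd" %in% methods) {
    cal <- kd_calibrate(ch)
    estimates$KD <- estimate_kd(ch, cal)
  }

  need_sem <- any(c("of", "od") %in% methods)
  if (need_sem) {
    for (form in forms) {
      log_stage("fitting %s SEM", form)
      fit <- fit_sem(ch, sem_spec(marker_names(ch), form))
      sem_fits[[form]] <- fit
      fs <- factor_scores(fit, ch)
      tag <- if (form == "linear") "linear" else "nonlinear"
      if ("of" %in% methods) {
        of <- estimate_of(fs, ch, form)
        estimates[[paste0("OF-", tag)]] <- of$estimates
      }
      if ("od" %in% methods) {
        log_stage("fitting null and augmented hazards (%s)", form)
        null_fit <- fit_gompertz(ch)
        aug_fit <- fit_gompertz(ch, covariates = list(fs = as.numeric(fs)))
        hazard_fits[[paste0("null_", form)]] <- null_fit
        hazard_fits[[paste0("augmented_", form)]] <- aug_fit
        estimates[[paste0("OD-", tag)]] <-
          estimate_od(fs, ch, null_fit, aug_fit, form)
      }
    }
  }

  tidy <- do.call(rbind, lapply(estimates, function(e)
    data.frame(subject_id = ch$subject_id, method = e$method,
               ba = e$ba, delta = e$delta)))
  utils::write.csv(tidy, file.path(out_dir, "ba_estimates.csv"),
                   row.names = FALSE)

  log_stage("fitting gap hazard models and evaluating")
  eval_tabs <- list()
  gap_rows <- list()
  e65_rows <- list()
  auc_rows <- list()
  for (nm in names(estimates)) {
    e <- estimates[[nm]]
    gfit <- fit_gompertz(ch, covariates = list(delta = e$delta))
    hazard_fits[[paste0("gap_", nm)]] <- gfit
    gap_rows[[nm]] <- data.frame(
      method = nm, phi = gfit$coef[["delta"]], beta = gfit$beta,
      k = gfit$k, aic = gfit$aic, bic = gfit$bic)
    e65_rows[[nm]] <- cbind(method = nm, e65_delta_curve(gfit))
    rs <- mortality_risk_score(gfit, ch,
                               covariates = list(delta = e$delta))
    ok <- !is.na(rs$label)
    for (band in list(c(0.8, 0.9), c(0.9, 1), c(0, 1))) {
      auc_rows[[paste(nm, band[1], band[2])]] <- data.frame(
        method = nm, spec_lo = band[1], spec_hi = band[2],
        auc = as.numeric(roc_auc(rs$score[ok], rs$label[ok], band)))
    }
  }
  eval_tabs$gap_hazards <- do.call(rbind, gap_rows)
  eval_tabs$e65 <- do.call(rbind, e65_rows)
  eval_tabs$auc <- do.call(rbind, auc_rows)
  utils::write.csv(eval_tabs$gap_hazards,
                   file.path(out_dir, "gap_hazard_models.csv"),
                   row.names = FALSE)
  utils::write.csv(eval_tabs$e65, file.path(out_dir, "e65_curves.csv"),
                   row.names = FALSE)
  utils::write.csv(eval_tabs$auc, file.path(out_dir, "auc_by_band.csv"),
                   row.names = FALSE)

  covs <- attr(ch, "covariates")
  if (all(c("sex", "race", "education") %in% covs)) {
    eval_tabs$disparity <- disparity_regression(estimates, ch)
    utils::write.csv(eval_tabs$disparity,
                     file.path(out_dir, "disparity_models.csv"),
                     row.names = FALSE)
  }

  manifest <- c(
    sprintf("bioage %s", as.character(utils::packageVersion("bioage"))),
    sprintf("R %s", paste(R.version$major, R.version$minor, sep = ".")),
    sprintf("seed: %s", config$seed %||% "none"),
    sprintf("methods: %s", paste(methods, collapse = ", ")),
    sprintf("forms: %s", paste(forms, collapse = ", ")),
    sprintf("n_in: %d, n_out: %d (age drops %d, incomplete %d, recoded %d)",
            rep$n_in, rep$n_out, rep$dropped_age, rep$dropped_incomplete,
            rep$recoded_censored))
  writeLines(manifest, file.path(out_dir, "manifest.txt"))
  log_stage("done; outputs in %s", out_dir)

  invisible(list(cohort = ch, estimates = estimates, sem_fits = sem_fits,
                 hazard_fits = hazard_fits, evaluation = eval_tabs,
                 filter_report = rep))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
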