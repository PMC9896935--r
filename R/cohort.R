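#' Column configuration for cohort files
#'
#' Maps the logical roles a cohort analysis needs (baseline age, follow-up
#' duration, event indicator, optional cause-exclusion flag, the biomarker
#' panel, covariates) onto the column names of a delimited or Stata file.
#'
#' @param age Column holding chronological age at baseline, in years.
#' @param duration Column holding follow-up duration, in years.
#' @param event Column holding the death indicator (0/1).
#' @param markers Character vector of biomarker column names (at least one).
#' @param cause_flag Optional column flagging deaths from causes excluded
#'   from age-related mortality (HIV, violence, accidents); `NULL` if absent.
#' @param covariates Character vector of categorical covariate columns
#'   (e.g. sex, race/ethnicity, education); may be empty.
#' @param subject_id Optional column with subject labels; row numbers are
#'   used when `NULL`.
#' @param log_markers Character vector (subset of `markers`) to
#'   log-transform on read; empty by default.
#' @param orientation Optional named numeric vector of +1/-1 per marker:
#'   +1 means higher values indicate worse physiological state (the common
#'   case), -1 the reverse (e.g. forced expiratory volume, albumin).
#'   Defaults to +1 for every marker.
#' @return An object of class `column_config`.
#' @export
column_config <- function(age, duration, event, markers,
                          cause_flag = NULL, covariates = character(),
                          subject_id = NULL, log_markers = character(),
                          orientation = NULL) {
  stopifnot(is.character(age), length(age) == 1L,
            is.character(duration), length(duration) == 1L,
            is.character(event), length(event) == 1L)
  if (length(markers) < 1L)
    stop("`markers` must name at least one biomarker column")
  if (anyDuplicated(markers))
    stop("duplicate marker names in `markers`")
  if (length(log_markers) && !all(log_markers %in% markers))
    stop("`log_markers` must be a subset of `markers`")
  if (is.null(orientation)) {
    orientation <- rep(1, length(markers))
    names(orientation) <- markers
  } else {
    if (!all(sort(names(orientation)) == sort(markers)) ||
        !all(orientation %in% c(-1, 1)))
      stop("`orientation` must be a named vector of +1/-1, one per marker")
    orientation <- orientation[markers]
  }
  structure(list(age = age, duration = duration, event = event,
                 markers = markers, cause_flag = cause_flag,
                 covariates = covariates, subject_id = subject_id,
                 log_markers = log_markers, orientation = orientation),
            class = "column_config")
}

#' Construct a cohort object
#'
#' A `cohort` is a data frame in canonical layout — `subject_id`, `ca_t0`
#' (baseline chronological age, years), `duration` (years under
#' observation), `dead` (0/1), `excluded_cause` (0/1) — plus one column per
#' biomarker and per covariate, with the marker/covariate names and marker
#' orientations carried as attributes.
#'
#' @param data Data frame already in canonical layout.
#' @param markers Character vector naming the biomarker columns.
#' @param covariates Character vector naming categorical covariate columns.
#' @param orientation Named +1/-1 vector per marker (+1 = higher is worse).
#' @return An object of classes `cohort` and `data.frame`.
#' @export
cohort <- function(data, markers, covariates = character(),
                   orientation = NULL) {
  stopifnot(is.data.frame(data))
  needed <- c("ca_t0", "duration", "dead", markers, covariates)
  miss <- setdiff(needed, names(data))
  if (length(miss))
    stop("cohort data is missing column(s): ", paste(miss, collapse = ", "))
  if (is.null(data$subject_id)) data$subject_id <- seq_len(nrow(data))
  if (is.null(data$excluded_cause)) data$excluded_cause <- 0L
  if (any(is.finite(data$duration) & data$duration < 0))
    stop("negative follow-up duration found")
  d <- data$dead[!is.na(data$dead)]
  if (!all(d %in% c(0, 1)))
    stop("`dead` must be a 0/1 indicator")
  if (is.null(orientation)) {
    orientation <- rep(1, length(markers))
    names(orientation) <- markers
  }
  structure(data, markers = markers, covariates = covariates,
            orientation = orientation[markers],
            class = c("cohort", "data.frame"))
}

#' Extract the biomarker matrix of a cohort
#' @param x A `cohort`.
#' @return Numeric matrix, one column per marker.
#' @export
marker_matrix <- function(x) {
  stopifnot(inherits(x, "cohort"))
  as.matrix(as.data.frame(x)[, attr(x, "markers"), drop = FALSE])
}

#' Marker names of a cohort
#' @param x A `cohort`.
#' @export
marker_names <- function(x) attr(x, "markers")

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d subjects, %d biomarkers (%s)\n", nrow(x),
              length(attr(x, "markers")),
              paste(attr(x, "markers"), collapse = ", ")))
  cat(sprintf("  deaths: %d (%d excluded-cause), covariates: %s\n",
              sum(x$dead == 1, na.rm = TRUE),
              sum(x$excluded_cause == 1 & x$dead == 1, na.rm = TRUE),
              if (length(attr(x, "covariates")))
                paste(attr(x, "covariates"), collapse = ", ") else "none"))
  invisible(x)
}

#' Read a cohort file
#'
#' Reads a delimited text file (`.csv`, `.tsv`, `.txt`) or a Stata file
#' (`.dta`, via the haven package) and maps its columns to the canonical
#' cohort layout using a [column_config()]. No eligibility filtering is
#' applied; rows are kept in file order.
#'
#' @param path Path to the file.
#' @param config A [column_config()].
#' @return A [cohort()].
#' @export
read_cohort <- function(path, config) {
  stopifnot(inherits(config, "column_config"))
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    dta = {
      if (!requireNamespace("haven", quietly = TRUE))
        stop("reading .dta files requires the haven package")
      as.data.frame(haven::read_dta(path))
    },
    tsv = utils::read.delim(path, stringsAsFactors = FALSE),
    utils::read.csv(path, stringsAsFactors = FALSE))
  roles <- c(age = config$age, duration = config$duration,
             event = config$event)
  if (!is.null(config$cause_flag)) roles <- c(roles, cause_flag = config$cause_flag)
  if (!is.null(config$subject_id)) roles <- c(roles, subject_id = config$subject_id)
  mapped <- c(roles, config$markers, config$covariates)
  miss <- setdiff(unname(mapped), names(raw))
  if (length(miss))
    stop("mapped column(s) absent from file: ", paste(miss, collapse = ", "))

  num_col <- function(col) {
    v <- raw[[col]]
    if (is.numeric(v)) return(as.numeric(v))
    out <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & v != "" & is.na(out))
    if (length(bad))
      stop(sprintf("column '%s': unparseable numeric value in row(s) %s",
                   col, paste(utils::head(bad, 5L), collapse = ", ")))
    out
  }

  out <- data.frame(
    subject_id = if (!is.null(config$subject_id)) raw[[config$subject_id]]
                 else seq_len(nrow(raw)),
    ca_t0 = num_col(config$age),
    duration = num_col(config$duration),
    dead = num_col(config$event),
    excluded_cause = if (!is.null(config$cause_flag))
      num_col(config$cause_flag) else 0L,
    stringsAsFactors = FALSE)
  for (m in config$markers) {
    v <- num_col(m)
    if (m %in% config$log_markers) v <- log(v)
    out[[m]] <- v
  }
  for (cv in config$covariates) out[[cv]] <- as.character(raw[[cv]])
  cohort(out, markers = config$markers, covariates = config$covariates,
         orientation = config$orientation)
}

#' Write a cohort to a CSV file
#'
#' Inverse of [read_cohort()] for the delimited case: values round-trip.
#'
#' @param x A `cohort`.
#' @param path Output path (CSV).
#' @export
write_cohort <- function(x, path) {
  stopifnot(inherits(x, "cohort"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Apply the eligibility filters
#'
#' Restricts a cohort to the analysis sample: baseline age within
#' `[age_min, age_max]`, complete cases on age and every biomarker, and —
#' following the competing-cause convention — deaths from excluded causes
#' (HIV, violence, accidents) recoded as censored at their observed
#' duration rather than deleted (`excluded_deaths = "censor"`, the
#' default) or dropped entirely (`"drop"`).
#'
#' @param x A `cohort`.
#' @param age_min,age_max Age bounds in years (inclusive).
#' @param excluded_deaths `"censor"` or `"drop"`.
#' @return The filtered `cohort`, with a `filter_report` attached as
#'   attribute `"filter_report"` counting subjects dropped per rule and
#'   excluded-cause deaths recoded.
#' @export
apply_eligibility_filters <- function(x, age_min = 30, age_max = 75,
                                      excluded_deaths = c("censor", "drop")) {
  stopifnot(inherits(x, "cohort"), is.finite(age_min), is.finite(age_max),
            age_min < age_max)
  excluded_deaths <- match.arg(excluded_deaths)
  n_in <- nrow(x)
  mk <- attr(x, "markers")

  age_ok <- !is.na(x$ca_t0) & x$ca_t0 >= age_min & x$ca_t0 <= age_max
  n_age <- sum(!age_ok)
  keep1 <- x[age_ok, , drop = FALSE]

  comp <- stats::complete.cases(as.data.frame(keep1)[, c("ca_t0", mk), drop = FALSE])
  n_incomplete <- sum(!comp)
  keep2 <- keep1[comp, , drop = FALSE]

  n_cause_drop <- 0L
  n_recoded <- 0L
  is_excl_death <- keep2$excluded_cause == 1 & keep2$dead == 1
  if (excluded_deaths == "drop") {
    n_cause_drop <- sum(is_excl_death)
    keep2 <- keep2[!is_excl_death, , drop = FALSE]
  } else {
    n_recoded <- sum(is_excl_death)
    keep2$dead[is_excl_death] <- 0
  }

  if (nrow(keep2) == 0L)
    stop("no subjects remain after eligibility filtering")
  for (m in mk)
    if (stats::var(keep2[[m]]) <= 0)
      stop("marker has zero variance after filtering: ", m)

  report <- structure(list(n_in = n_in, n_out = nrow(keep2),
                           dropped_age = n_age,
                           dropped_incomplete = n_incomplete,
                           dropped_excluded_cause = n_cause_drop,
                           recoded_censored = n_recoded,
                           age_min = age_min, age_max = age_max,
                           excluded_deaths = excluded_deaths),
                      class = "filter_report")
  out <- cohort(as.data.frame(keep2), markers = mk,
                covariates = attr(x, "covariates"),
                orientation = attr(x, "orientation"))
  attr(out, "filter_report") <- report
  out
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("<filter_report> %d in -> %d out\n", x$n_in, x$n_out))
  cat(sprintf("  age outside [%g, %g]: %d\n", x$age_min, x$age_max,
              x$dropped_age))
  cat(sprintf("  incomplete age/markers: %d\n", x$dropped_incomplete))
  if (x$excluded_deaths == "drop")
    cat(sprintf("  excluded-cause deaths dropped: %d\n",
                x$dropped_excluded_cause))
  else
    cat(sprintf("  excluded-cause deaths recoded censored: %d\n",
                x$recoded_censored))
  invisible(x)
}
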