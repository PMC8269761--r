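trial_log_cols <- c("subject_id", "protocol", "eye", "test_rep", "trial",
                    "phase", "distance_cm", "line_logmar", "demand_logmar",
                    "correct")

#' Flatten a test result into trial-log rows
#'
#' @param result A `va_test_result`.
#' @param subject_id,test_rep Identifiers stamped on every row.
#' @return A tibble in the shared trial-log schema (`distance_cm` is NA for
#'   iSight rows, `line_logmar` NA for tracker rows).
#' @export
trial_log_rows <- function(result, subject_id = "S01", test_rep = 1L) {
  stopifnot(inherits(result, "va_test_result"))
  tr <- result$trials
  tibble::tibble(
    subject_id = subject_id,
    protocol = result$protocol,
    eye = result$eye,
    test_rep = as.integer(test_rep),
    trial = tr$trial,
    phase = tr$phase,
    distance_cm = if ("distance_cm" %in% names(tr)) tr$distance_cm else NA_real_,
    line_logmar = if ("line_logmar" %in% names(tr)) tr$line_logmar else NA_real_,
    demand_logmar = if ("demand_logmar" %in% names(tr)) {
      tr$demand_logmar
    } else {
      tr$line_logmar
    },
    correct = tr$correct
  )
}

#' Write / read a trial-log CSV
#'
#' Fixed-schema CSV holding the per-letter record of one or more tests;
#' round-trips losslessly.
#'
#' @param trials A tibble in the trial-log schema (see [trial_log_rows()]).
#' @param path File path.
#' @return `read_trial_log()` returns the tibble (empty, with a warning, for
#'   an empty file); `write_trial_log()` returns `path` invisibly.
#' @export
write_trial_log <- function(trials, path) {
  stopifnot(is.data.frame(trials))
  missing <- setdiff(trial_log_cols, names(trials))
  if (length(missing) > 0) {
    stop("trial log is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  readr::write_csv(trials[, trial_log_cols], path)
  invisible(path)
}

#' @rdname write_trial_log
#' @export
read_trial_log <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (file.size(path) == 0) {
    warning("empty trial log: ", path)
    return(tibble::tibble(
      subject_id = character(), protocol = character(), eye = character(),
      test_rep = integer(), trial = integer(), phase = character(),
      distance_cm = numeric(), line_logmar = numeric(),
      demand_logmar = numeric(), correct = logical()
    ))
  }
  header <- strsplit(readLines(path, n = 1), ",", fixed = TRUE)[[1]]
  missing <- setdiff(trial_log_cols, trimws(header))
  if (length(missing) > 0) {
    stop("trial log is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- readr::read_csv(
    path,
    col_types = readr::cols(
      subject_id = readr::col_character(),
      protocol = readr::col_character(),
      eye = readr::col_character(),
      test_rep = readr::col_integer(),
      trial = readr::col_integer(),
      phase = readr::col_character(),
      distance_cm = readr::col_double(),
      line_logmar = readr::col_double(),
      demand_logmar = readr::col_double(),
      correct = readr::col_logical()
    )
  )
  missing <- setdiff(trial_log_cols, names(out))
  if (length(missing) > 0) {
    stop("trial log is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  probs <- readr::problems(out)
  if (nrow(probs) > 0) {
    stop("malformed trial log row(s) at line(s): ",
         paste(unique(probs$row), collapse = ", "), call. = FALSE)
  }
  out
}

#' Write an agreement report as JSON
#'
#' Serialises the output of [assemble_tables()] (plus provenance fields) to
#' a JSON report. The interocular difference sign convention (right minus
#' left) is recorded in the header.
#'
#' @param report List from [assemble_tables()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_agreement_report <- function(report, path) {
  payload <- list(
    schema = "acuitysim-agreement-report/1",
    iad_sign_convention = "right_minus_left",
    bias_conventions = list(retest = "test1_minus_test2",
                            cross_method = "isight_minus_tracker"),
    n_analysed = report$n_analysed,
    table1 = report$table1, table2 = report$table2, table3 = report$table3
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Write / read a cohort CSV (one row per observer)
#'
#' @param cohort List of observers from [sample_cohort()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  scr <- attr(cohort, "screening")
  if (is.null(scr)) stop("cohort has no screening record", call. = FALSE)
  readr::write_csv(scr, path)
  invisible(path)
}
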