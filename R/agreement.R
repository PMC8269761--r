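#' Signed paired differences under a stated convention
#'
#' Bias sign conventions follow the study analysis: for test-retest data the
#' first test minus the second; for the cross-method comparison the tracker
#' score is subtracted from the iSight score.
#'
#' @param x,y Equal-length numeric vectors of acuities (logMAR). `x` is the
#'   first test (or the iSight score), `y` the second test (or the tracker
#'   score).
#' @param convention `"test1_minus_test2"` or `"isight_minus_tracker"`;
#'   both compute `x - y`, the argument documents which is which.
#' @return Numeric vector of signed differences.
#' @export
paired_differences <- function(x, y,
                               convention = c("test1_minus_test2",
                                              "isight_minus_tracker")) {
  convention <- match.arg(convention)
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) {
    stop("`x` and `y` must have equal length", call. = FALSE)
  }
  x - y
}

#' Bland-Altman bias and limits of agreement
#'
#' The mean bias is the mean of the paired differences; the limits of
#' agreement are the bias plus/minus 1.96 times the sample standard
#' deviation (n - 1 denominator) of the differences. About 95% of
#' differences between the two methods are expected inside the limits.
#'
#' @param diffs Numeric vector of paired differences (length >= 2).
#' @return List: `mean_bias`, `sd_diff`, `upper_loa`, `lower_loa`, `n`.
#' @export
bland_altman <- function(diffs) {
  stopifnot(is.numeric(diffs))
  if (length(diffs) < 2) stop("need at least 2 differences", call. = FALSE)
  m <- mean(diffs)
  s <- stats::sd(diffs)
  loa <- loa_from_summary(m, s)
  list(mean_bias = m, sd_diff = s,
       upper_loa = loa$upper_loa, lower_loa = loa$lower_loa,
       n = length(diffs))
}

#' Limits of agreement from summary statistics
#'
#' Worked-example entry point for printed bias/SD pairs:
#' `bias +- 1.96 * sd`.
#'
#' @param mean_bias Mean of the paired differences.
#' @param sd_diff Standard deviation of the paired differences (>= 0).
#' @return List with `upper_loa` and `lower_loa`.
#' @examples
#' loa_from_summary(0.013, 0.131)$upper_loa  # 0.270 at 3 dp
#' @export
loa_from_summary <- function(mean_bias, sd_diff) {
  stopifnot(is.numeric(mean_bias), is.numeric(sd_diff))
  if (any(sd_diff < 0)) stop("`sd_diff` must be non-negative", call. = FALSE)
  list(upper_loa = mean_bias + 1.96 * sd_diff,
       lower_loa = mean_bias - 1.96 * sd_diff)
}

#' Two-sided paired t-test on a vector of differences
#'
#' `t = mean / (sd / sqrt(n))` with `n - 1` degrees of freedom. Degenerate
#' zero-variance inputs follow the conventions: all-zero differences give
#' `p = 1`; constant nonzero differences give `p = 0` (infinite t).
#'
#' @param diffs Numeric vector of paired differences (length >= 2).
#' @return List: `t`, `p`, `df`, `n`.
#' @export
paired_t_test <- function(diffs) {
  stopifnot(is.numeric(diffs))
  n <- length(diffs)
  if (n < 2) stop("need at least 2 differences", call. = FALSE)
  m <- mean(diffs)
  s <- stats::sd(diffs)
  df <- n - 1
  if (s == 0) {
    if (m == 0) return(list(t = 0, p = 1, df = df, n = n))
    return(list(t = sign(m) * Inf, p = 0, df = df, n = n))
  }
  t <- m / (s / sqrt(n))
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, p = p, df = df, n = n)
}

#' Whole-line difference distribution and within-one-line proportion
#'
#' Each logMAR difference is mapped to a signed whole number of lines
#' (`diff / line_step`, rounded to the nearest integer with the
#' round-half-even rule; both protocols emit whole-line scores so ties only
#' arise for letter-scored inputs). Returns the signed histogram and the
#' percentage of differences within one line, rounded to a whole percent.
#'
#' @param diffs Numeric vector of paired differences (logMAR).
#' @param line_step One line in logMAR. Default 0.1.
#' @return List: `histogram` (tibble `lines`, `count`),
#'   `pct_within_one_line`, `n`.
#' @export
line_difference_distribution <- function(diffs, line_step = 0.1) {
  stopifnot(is.numeric(diffs), line_step > 0)
  lines <- round(diffs / line_step)
  tab <- table(factor(lines, levels = seq(min(c(lines, 0)), max(c(lines, 0)))))
  hist <- tibble::tibble(lines = as.integer(names(tab)),
                         count = as.integer(tab))
  pct <- if (length(lines) == 0) NA_real_ else round(100 * mean(abs(lines) <= 1))
  list(histogram = hist, pct_within_one_line = pct, n = length(diffs))
}

analysis_subset <- function(results) {
  stopifnot(is.data.frame(results))
  res <- results[!results$excluded & !is.na(results$measured_logmar), , drop = FALSE]
  if (nrow(res) == 0) stop("no analysable results", call. = FALSE)
  res
}

#' Interocular acuity difference per subject
#'
#' Signed right-minus-left difference of the measured acuities for one
#' protocol and repetition, with mean and SD across subjects. Subjects
#' missing either eye are dropped with a warning.
#'
#' @param results A `cohort_results` tibble from [run_study()].
#' @param app `"isight"` or `"tracker"`.
#' @param test_rep Repetition number (1 or 2).
#' @return List: `per_subject` (tibble `subject_id`, `iad`), `mean`, `sd`,
#'   `n`.
#' @export
interocular_difference <- function(results, app, test_rep) {
  app <- match.arg(app, c("isight", "tracker"))
  res <- analysis_subset(results)
  res <- res[res$app == app & res$test_rep == test_rep, , drop = FALSE]
  wide <- tidyr::pivot_wider(
    res[, c("subject_id", "eye", "measured_logmar")],
    names_from = "eye", values_from = "measured_logmar"
  )
  if (!all(c("right", "left") %in% names(wide))) {
    stop("need both eyes for at least one subject", call. = FALSE)
  }
  incomplete <- is.na(wide$right) | is.na(wide$left)
  if (any(incomplete)) {
    warning(sum(incomplete), " subject(s) dropped: missing one eye")
    wide <- wide[!incomplete, , drop = FALSE]
  }
  per <- tibble::tibble(subject_id = wide$subject_id,
                        iad = wide$right - wide$left)
  list(per_subject = per, mean = mean(per$iad), sd = stats::sd(per$iad),
       n = nrow(per))
}

# Wide per-subject scores for one app/eye across two repetitions.
scores_wide <- function(results, app_, eye_, reps = c(1, 2)) {
  res <- analysis_subset(results)
  res <- res[res$app == app_ & res$eye == eye_ & res$test_rep %in% reps, ,
             drop = FALSE]
  tidyr::pivot_wider(
    res[, c("subject_id", "test_rep", "measured_logmar")],
    names_from = "test_rep", values_from = "measured_logmar",
    names_prefix = "t"
  )
}

#' Assemble the study's three report tables
#'
#' * `table1`: per protocol and eye — test 1 and test 2 mean and SD, the
#'   test-retest paired t p-value, mean bias (test 1 minus test 2) with SD,
#'   and the limits of agreement.
#' * `table2`: per eye and repetition — cross-method differences (iSight
#'   minus tracker): bias, SD, limits of agreement, paired t p-value.
#' * `table3`: per protocol — interocular acuity difference (right minus
#'   left) on each test, and the per-subject test 1 minus test 2 IAD
#'   difference, each as mean and SD, with the paired t p-value.
#'
#' All values are returned unrounded; round at display time.
#'
#' @param results A `cohort_results` tibble from [run_study()] with at
#'   least two non-excluded subjects.
#' @return List of tibbles `table1`, `table2`, `table3` plus `n_analysed`.
#' @export
assemble_tables <- function(results) {
  res <- analysis_subset(results)
  n_subj <- length(unique(res$subject_id))
  if (n_subj < 2) stop("need at least 2 non-excluded subjects", call. = FALSE)

  t1 <- list()
  for (app_ in c("isight", "tracker")) {
    for (eye_ in c("right", "left")) {
      w <- scores_wide(results, app_, eye_)
      w <- w[!is.na(w$t1) & !is.na(w$t2), , drop = FALSE]
      d <- paired_differences(w$t1, w$t2, "test1_minus_test2")
      ba <- bland_altman(d)
      tt <- paired_t_test(d)
      t1[[length(t1) + 1L]] <- tibble::tibble(
        app = app_, eye = eye_, n = nrow(w),
        test1_mean = mean(w$t1), test1_sd = stats::sd(w$t1),
        test2_mean = mean(w$t2), test2_sd = stats::sd(w$t2),
        p_value = tt$p,
        mean_bias = ba$mean_bias, sd_diff = ba$sd_diff,
        upper_loa = ba$upper_loa, lower_loa = ba$lower_loa,
        pct_within_one_line = line_difference_distribution(d)$pct_within_one_line
      )
    }
  }

  t2 <- list()
  for (eye_ in c("right", "left")) {
    for (rep_ in c(1, 2)) {
      wi <- scores_wide(results, "isight", eye_, rep_)
      wt <- scores_wide(results, "tracker", eye_, rep_)
      names(wi)[2] <- "isight"
      names(wt)[2] <- "tracker"
      w <- dplyr::inner_join(wi, wt, by = "subject_id")
      w <- w[!is.na(w$isight) & !is.na(w$tracker), , drop = FALSE]
      d <- paired_differences(w$isight, w$tracker, "isight_minus_tracker")
      ba <- bland_altman(d)
      tt <- paired_t_test(d)
      t2[[length(t2) + 1L]] <- tibble::tibble(
        eye = eye_, test_rep = rep_, n = nrow(w),
        mean_bias = ba$mean_bias, sd_diff = ba$sd_diff,
        upper_loa = ba$upper_loa, lower_loa = ba$lower_loa,
        p_value = tt$p
      )
    }
  }

  t3 <- list()
  for (app_ in c("isight", "tracker")) {
    i1 <- interocular_difference(results, app_, 1)
    i2 <- interocular_difference(results, app_, 2)
    w <- dplyr::inner_join(i1$per_subject, i2$per_subject,
                           by = "subject_id", suffix = c("_t1", "_t2"))
    d <- paired_differences(w$iad_t1, w$iad_t2, "test1_minus_test2")
    tt <- paired_t_test(d)
    t3[[length(t3) + 1L]] <- tibble::tibble(
      app = app_, n = nrow(w),
      iad_test1_mean = i1$mean, iad_test1_sd = i1$sd,
      iad_test2_mean = i2$mean, iad_test2_sd = i2$sd,
      iad_diff_mean = mean(d), iad_diff_sd = stats::sd(d),
      p_value = tt$p
    )
  }

  list(
    table1 = dplyr::bind_rows(t1),
    table2 = dplyr::bind_rows(t2),
    table3 = dplyr::bind_rows(t3),
    n_analysed = n_subj
  )
}
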