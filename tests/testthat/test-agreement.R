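test_that("paired differences honour the stated sign conventions", {
  expect_equal(paired_differences(c(1, 2), c(1, 2)), c(0, 0))
  expect_equal(paired_differences(0.5, 0.4, "isight_minus_tracker"), 0.1)
  set.seed(8)
  x <- rnorm(50); y <- rnorm(50)
  brute <- vapply(seq_along(x), function(i) x[i] - y[i], numeric(1))
  expect_identical(paired_differences(x, y), brute)
  expect_error(paired_differences(1:3, 1:2), "equal length")
})

test_that("Bland-Altman limits reproduce the printed worked examples", {
  # Cross-method comparison, right eye: bias 0.013, SD 0.131 -> upper 0.270
  ex1 <- loa_from_summary(0.013, 0.131)
  expect_equal(round(ex1$upper_loa, 3), 0.270)
  # Right eye second test: bias -0.019, SD 0.164 -> upper 0.302
  ex2 <- loa_from_summary(-0.019, 0.164)
  expect_equal(round(ex2$upper_loa, 3), 0.302)
  # Left eye first test: bias -0.009, SD 0.106 -> lower -0.217
  ex3 <- loa_from_summary(-0.009, 0.106)
  expect_equal(round(ex3$lower_loa, 3), -0.217)
  # symmetry around the bias
  ex0 <- loa_from_summary(0, 0.2)
  expect_equal(ex0$upper_loa, 1.96 * 0.2)
  expect_equal(ex0$lower_loa, -1.96 * 0.2)
  expect_error(loa_from_summary(0, -0.1), "non-negative")
})

test_that("bland_altman matches its closed forms and the summary route", {
  const <- bland_altman(rep(0.07, 5))
  expect_equal(const$mean_bias, 0.07)
  expect_equal(const$sd_diff, 0)
  expect_equal(const$upper_loa, 0.07)
  expect_equal(const$lower_loa, 0.07)
  two <- bland_altman(c(-0.3, 0.3))
  expect_equal(two$mean_bias, 0)
  expect_equal(two$upper_loa, 1.96 * 0.3 * sqrt(2), tolerance = 1e-12)
  expect_error(bland_altman(0.1), "at least 2")
  # compositional consistency with paired_differences + loa_from_summary
  set.seed(9)
  x <- rnorm(30, 0.4, 0.2); y <- rnorm(30, 0.4, 0.2)
  d <- paired_differences(x, y)
  ba <- bland_altman(d)
  loa <- loa_from_summary(mean(d), sd(d))
  expect_equal(ba$upper_loa, loa$upper_loa, tolerance = 1e-12)
  expect_equal(ba$lower_loa, loa$lower_loa, tolerance = 1e-12)
})

test_that("paired t-test agrees with the reference implementation to 1e-10", {
  set.seed(10)
  for (i in 1:100) {
    n <- sample(3:40, 1)
    d <- rnorm(n, sd = runif(1, 0.01, 1))
    ours <- paired_t_test(d)
    ref <- stats::t.test(d)
    expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
  }
  # known vector, cross-checked the same way
  d <- c(0.1, 0.2, 0.0, 0.1)
  ours <- paired_t_test(d)
  ref <- stats::t.test(d)
  expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
})

test_that("degenerate difference vectors follow the stated conventions", {
  expect_equal(paired_t_test(rep(0, 4))$p, 1)
  expect_equal(paired_t_test(rep(0.2, 4))$p, 0)
  expect_equal(paired_t_test(rep(-0.2, 4))$t, -Inf)
  expect_error(paired_t_test(0.1), "at least 2")
})

test_that("null-simulation p-values are roughly uniform", {
  set.seed(123)
  p <- replicate(400, paired_t_test(rnorm(20))$p)
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.001)
})

test_that("line-difference distribution bins and percentages are exact", {
  all0 <- line_difference_distribution(rep(0, 10))
  expect_equal(all0$pct_within_one_line, 100)
  # 27 of 32 within one line -> 84%
  d <- c(rep(0, 20), rep(0.1, 7), rep(0.2, 5))
  ld <- line_difference_distribution(d)
  expect_equal(ld$pct_within_one_line, 84)
  expect_equal(sum(ld$histogram$count), 32)
  # percentages recompute from the histogram exactly
  h <- ld$histogram
  expect_equal(round(100 * sum(h$count[abs(h$lines) <= 1]) / sum(h$count)),
               ld$pct_within_one_line)
  # round-half-even at the bin edge: 0.25 -> 2.5 lines -> 2
  edge <- line_difference_distribution(0.25)
  expect_equal(edge$histogram$count[edge$histogram$lines == 2], 1L)
  # signed bins kept separate
  signs <- line_difference_distribution(c(-0.2, 0.2))
  expect_equal(signs$histogram$count[signs$histogram$lines == -2], 1L)
  expect_equal(signs$histogram$count[signs$histogram$lines == 2], 1L)
})

make_results <- function(tbl) {
  tbl$final_distance_cm <- NA_real_
  tbl$sentinel <- "none"
  tbl$excluded <- FALSE
  tbl$exclusion_reason <- NA_character_
  tbl
}

test_that("interocular difference matches a brute-force per-subject loop", {
  set.seed(14)
  subj <- sprintf("S%02d", 1:10)
  grid <- seq(0, 0.7, by = 0.1)
  tbl <- expand.grid(subject_id = subj, eye = c("right", "left"),
                     app = c("isight", "tracker"), test_rep = 1:2,
                     stringsAsFactors = FALSE)
  tbl$measured_logmar <- sample(grid, nrow(tbl), replace = TRUE)
  res <- make_results(tibble::as_tibble(tbl))
  iad <- interocular_difference(res, "isight", 1)
  brute <- vapply(subj, function(s) {
    r <- res$measured_logmar[res$subject_id == s & res$eye == "right" &
                               res$app == "isight" & res$test_rep == 1]
    l <- res$measured_logmar[res$subject_id == s & res$eye == "left" &
                               res$app == "isight" & res$test_rep == 1]
    r - l
  }, numeric(1))
  expect_equal(sort(iad$per_subject$iad), sort(unname(brute)))
  expect_equal(iad$mean, mean(brute))
  expect_equal(iad$sd, sd(brute))
  # constant eyes give zero mean and SD
  res2 <- res
  res2$measured_logmar <- 0.3
  iad2 <- interocular_difference(res2, "tracker", 2)
  expect_equal(iad2$mean, 0)
  expect_equal(iad2$sd, 0)
})

test_that("assembled tables satisfy their internal identities", {
  res <- run_study(study_config(n_subjects = 8, seed = 33))
  tabs <- assemble_tables(res)
  for (tb in list(tabs$table1, tabs$table2)) {
    expect_equal(tb$upper_loa, tb$mean_bias + 1.96 * tb$sd_diff,
                 tolerance = 1e-12)
    expect_equal(tb$lower_loa, tb$mean_bias - 1.96 * tb$sd_diff,
                 tolerance = 1e-12)
  }
  expect_equal(nrow(tabs$table1), 4)
  expect_equal(nrow(tabs$table2), 4)
  expect_equal(nrow(tabs$table3), 2)
  expect_equal(tabs$table3$iad_diff_mean,
               tabs$table3$iad_test1_mean - tabs$table3$iad_test2_mean,
               tolerance = 1e-12)
  expect_true(all(tabs$table1$pct_within_one_line >= 0 &
                    tabs$table1$pct_within_one_line <= 100))
})

test_that("comparing a protocol against itself gives near-zero bias", {
  # run the same protocol twice per eye and difference the repetitions:
  # the null comparison should show only Monte-Carlo-sized bias
  set.seed(55)
  o <- observer(psychometric_eye(0.35, lapse_rate = 0),
                psychometric_eye(0.35, lapse_rate = 0))
  d <- replicate(60, run_isight_test(o, "right")$logmar -
                     run_isight_test(o, "right")$logmar)
  d <- d[!is.na(d)]
  ba <- bland_altman(d)
  expect_lt(abs(ba$mean_bias), 3 * ba$sd_diff / sqrt(length(d)) + 0.02)
})

test_that("insufficient data raises errors", {
  res <- run_study(study_config(n_subjects = 2, seed = 44))
  one <- res[res$subject_id == res$subject_id[1], ]
  expect_error(assemble_tables(one), "at least 2|no analysable")
})
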