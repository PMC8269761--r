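#' Study configuration
#'
#' Parameters of the simulated two-app repeated-measures agreement study:
#' cohort size, the screening window the Bangerter filters must bring the
#' better eye into, the minimum interocular acuity difference used to
#' simulate amblyopia, and the number of repetitions of each protocol per
#' eye.
#'
#' @param n_subjects Number of simulated participants. Default 36.
#' @param screening_floor Minimum screened acuity of the better eye after
#'   filtering (logMAR). Default 0.2, chosen so that test-phase improvements
#'   stay inside the tracker's 0.0 floor.
#' @param screening_ceiling Maximum screened acuity of either eye (logMAR);
#'   the phone cannot display letters above this. Default 0.7.
#' @param min_iad Minimum interocular acuity difference (logMAR). Default
#'   0.2 (two lines).
#' @param repetitions Tests per protocol per eye. Default 2.
#' @param seed Integer seed governing all randomness in [run_study()].
#' @param randomize_app_order,randomize_eye_order Randomise protocol order
#'   and which eye is tested first, per subject. Default `TRUE`.
#' @param cohort A [cohort_spec()].
#' @return A list of class `study_config`.
#' @export
study_config <- function(n_subjects = 36,
                         screening_floor = 0.2,
                         screening_ceiling = 0.7,
                         min_iad = 0.2,
                         repetitions = 2,
                         seed = 1L,
                         randomize_app_order = TRUE,
                         randomize_eye_order = TRUE,
                         cohort = cohort_spec()) {
  stopifnot(
    n_subjects >= 1, repetitions >= 1,
    screening_floor < screening_ceiling,
    min_iad >= 0
  )
  structure(
    list(
      n_subjects = as.integer(n_subjects),
      screening_floor = screening_floor,
      screening_ceiling = screening_ceiling,
      min_iad = min_iad,
      repetitions = as.integer(repetitions),
      seed = as.integer(seed),
      randomize_app_order = isTRUE(randomize_app_order),
      randomize_eye_order = isTRUE(randomize_eye_order),
      cohort = cohort
    ),
    class = "study_config"
  )
}

#' Descending single-letter screen of one eye
#'
#' The coarse screening measure used to select filters: one letter per line
#' from the chart top downward; the last correctly identified line is the
#' screening vision. Not a complete threshold measure (no confirm blocks).
#'
#' @inheritParams respond
#' @param top_line,bottom_line,line_step Chart geometry; defaults 0.7, 0.0,
#'   0.1 logMAR.
#' @return Screened acuity in logMAR; `Inf` when the first (largest) letter
#'   is missed, i.e. vision worse than the chart ceiling.
#' @export
screen_vision <- function(obs, side, top_line = 0.7, bottom_line = 0,
                          line_step = 0.1, session_jitter = 0) {
  lines <- round(seq(top_line, bottom_line, by = -line_step), 10)
  last_correct <- Inf
  for (ln in lines) {
    if (respond(obs, side, ln, session_jitter)) last_correct <- ln
    else break
  }
  last_correct
}

# Realised blur ladder for one subject-eye: nominal map plus calibration
# jitter, truncated at zero. Index 0 encodes "no filter".
subject_blur_ladder <- function(spec) {
  jitter <- stats::rnorm(length(spec$blur_map), 0, spec$filter_jitter_sd)
  pmax(0, spec$blur_map + jitter)
}

#' Screening phase: fit Bangerter filters to one observer
#'
#' Simulates the study's screening phase. Each eye gets a realised blur
#' ladder (nominal label map plus per-subject calibration jitter). Candidate
#' filter pairs (including "no filter" for either eye) are tried greedily
#' from weakest to strongest total blur; for each pair both eyes are
#' screened with [screen_vision()] and the first pair satisfying all of
#'
#' * better-eye screened acuity in `[screening_floor, screening_ceiling]`,
#' * worse-eye screened acuity at or below `screening_ceiling`, and
#' * interocular difference at least `min_iad`
#'
#' is assigned. Subjects for whom no pair works are flagged unscreenable.
#'
#' @param obs A [observer()] without filters.
#' @param config A [study_config()].
#' @param spec A [cohort_spec()] supplying the blur map and jitter SDs.
#' @return List with `observer` (filters attached), and `record`, a one-row
#'   tibble (id, filter labels, screened acuities, `unscreenable` flag).
#' @export
screen_and_fit_filters <- function(obs, config = study_config(), spec = cohort_spec()) {
  stopifnot(inherits(obs, "va_observer"), inherits(config, "study_config"))
  labels <- names(spec$blur_map)
  ladder_r <- subject_blur_ladder(spec)
  ladder_l <- subject_blur_ladder(spec)
  # blur option 0 = no filter
  blur_r <- c(0, ladder_r)
  blur_l <- c(0, ladder_l)
  combos <- expand.grid(i = seq_along(blur_r), j = seq_along(blur_l))
  combos$total <- blur_r[combos$i] + blur_l[combos$j]
  combos <- combos[order(combos$total, pmax(blur_r[combos$i], blur_l[combos$j])), ]

  make_obs <- function(i, j) {
    rf <- if (i > 1) bangerter_filter(labels[i - 1], blur_r[i], spec$inhomogeneity_sd)
    lf <- if (j > 1) bangerter_filter(labels[j - 1], blur_l[j], spec$inhomogeneity_sd)
    observer(obs$right_eye, obs$left_eye, rf, lf, id = obs$id, seed = obs$seed)
  }

  for (k in seq_len(nrow(combos))) {
    cand <- make_obs(combos$i[k], combos$j[k])
    s_r <- screen_vision(cand, "right", config$screening_ceiling, 0)
    s_l <- screen_vision(cand, "left", config$screening_ceiling, 0)
    if (is.infinite(s_r) || is.infinite(s_l)) next
    better <- min(s_r, s_l)
    iad <- abs(s_r - s_l)
    if (better >= config$screening_floor && better <= config$screening_ceiling &&
        max(s_r, s_l) <= config$screening_ceiling && iad >= config$min_iad) {
      rec <- tibble::tibble(
        subject_id = obs$id,
        re_true = obs$right_eye$true_logmar, le_true = obs$left_eye$true_logmar,
        re_filter = if (combos$i[k] > 1) labels[combos$i[k] - 1] else NA_character_,
        le_filter = if (combos$j[k] > 1) labels[combos$j[k] - 1] else NA_character_,
        re_screen = s_r, le_screen = s_l,
        unscreenable = FALSE
      )
      return(list(observer = cand, record = rec))
    }
  }
  rec <- tibble::tibble(
    subject_id = obs$id,
    re_true = obs$right_eye$true_logmar, le_true = obs$left_eye$true_logmar,
    re_filter = NA_character_, le_filter = NA_character_,
    re_screen = NA_real_, le_screen = NA_real_,
    unscreenable = TRUE
  )
  list(observer = obs, record = rec)
}

#' Run the full simulated study
#'
#' End-to-end replication of the study design on a synthetic cohort: sample
#' observers, screen and fit filters, then for each protocol (order
#' randomised per subject) test both eyes (first eye randomised) and repeat.
#' Each (eye, protocol, repetition) session draws its own filter
#' inhomogeneity jitter; tracker retests start from the previous result's
#' final distance. Subjects are excluded when unscreenable, when any test
#' hits a range sentinel, or when any iSight score is better than 0.0
#' logMAR (outside the tracker's range).
#'
#' @param config A [study_config()].
#' @return A tibble (class `cohort_results`) with one row per test:
#'   `subject_id, eye, app, test_rep, measured_logmar, final_distance_cm,
#'   sentinel, excluded, exclusion_reason`. The screening table is attached
#'   as attribute `"screening"`.
#' @export
run_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  set.seed(config$seed)
  cohort <- sample_cohort(config$n_subjects, config$cohort, config)
  screening <- attr(cohort, "screening")
  scale <- acuity_scale()
  rows <- list()

  for (obs in cohort) {
    unscreenable <- screening$unscreenable[screening$subject_id == obs$id]
    apps <- c("isight", "tracker")
    eyes <- c("right", "left")
    if (config$randomize_app_order && stats::runif(1) < 0.5) apps <- rev(apps)
    if (config$randomize_eye_order && stats::runif(1) < 0.5) eyes <- rev(eyes)
    if (unscreenable) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        subject_id = obs$id, eye = NA_character_, app = NA_character_,
        test_rep = NA_integer_, measured_logmar = NA_real_,
        final_distance_cm = NA_real_, sentinel = NA_character_,
        excluded = TRUE, exclusion_reason = "unscreenable"
      )
      next
    }
    for (app in apps) {
      for (rep in seq_len(config$repetitions)) {
        for (eye in eyes) {
          jit <- draw_session_jitter(obs, eye)
          if (app == "tracker") {
            # the study protocol starts every test at 30 cm; starting from
            # the previous result is a home-monitoring convenience only
            res <- run_tracker_test(obs, eye, scale, 30, jit)
          } else {
            res <- run_isight_test(obs, eye,
                                   top_line = config$screening_ceiling,
                                   session_jitter = jit)
          }
          rows[[length(rows) + 1L]] <- tibble::tibble(
            subject_id = obs$id, eye = eye, app = app, test_rep = rep,
            measured_logmar = res$logmar,
            final_distance_cm = res$final_distance_cm,
            sentinel = res$sentinel,
            excluded = FALSE, exclusion_reason = NA_character_
          )
        }
      }
    }
  }

  out <- dplyr::bind_rows(rows)
  # Subject-level exclusion rules.
  bad_sentinel <- unique(out$subject_id[!is.na(out$sentinel) & out$sentinel != "none"])
  bad_isight <- unique(out$subject_id[
    !is.na(out$measured_logmar) & out$app == "isight" & out$measured_logmar < 0
  ])
  out$excluded <- out$excluded |
    out$subject_id %in% bad_sentinel | out$subject_id %in% bad_isight
  out$exclusion_reason <- dplyr::case_when(
    !is.na(out$exclusion_reason) ~ out$exclusion_reason,
    out$subject_id %in% bad_isight ~ "isight score better than 0.0",
    out$subject_id %in% bad_sentinel ~ "score outside test range",
    .default = NA_character_
  )
  attr(out, "screening") <- screening
  class(out) <- c("cohort_results", class(out))
  out
}
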