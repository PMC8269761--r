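#' Psychometric eye model
#'
#' One eye of a simulated observer, parameterised as a standard
#' guess/lapse-corrected psychometric function over logMAR demand:
#' `p(correct | demand) = gamma + (1 - gamma - lambda) * F((demand - t) / sigma)`
#' where `F` is the logistic CDF, `t` the true acuity threshold, `sigma` the
#' psychometric spread in logMAR, `gamma` the guess rate and `lambda` the
#' lapse rate. Larger demand means a larger retinal letter, so `p` increases
#' with demand. The default guess rate is 1/6 because both simulated
#' protocols draw from a six-letter ETDRS set.
#'
#' `slope_sigma = 0` is accepted as the exact step-function limit: the
#' response is correct with probability `1 - lapse_rate` when
#' `demand >= true_logmar` and `guess_rate` otherwise.
#'
#' @param true_logmar True acuity threshold (logMAR; larger = worse).
#' @param slope_sigma Psychometric spread in logMAR (>= 0). Default 0.05,
#'   half a line.
#' @param guess_rate Probability of a correct response far below threshold
#'   demand. Default 1/6.
#' @param lapse_rate Probability of an error on a trivially easy letter.
#'   Default 0.01.
#' @return An object of class `psychometric_eye`.
#' @export
psychometric_eye <- function(true_logmar,
                             slope_sigma = 0.05,
                             guess_rate = 1 / 6,
                             lapse_rate = 0.01) {
  stopifnot(
    is.numeric(true_logmar), length(true_logmar) == 1, is.finite(true_logmar),
    is.numeric(slope_sigma), length(slope_sigma) == 1, slope_sigma >= 0,
    is.numeric(guess_rate), guess_rate >= 0,
    is.numeric(lapse_rate), lapse_rate >= 0
  )
  if (guess_rate + lapse_rate >= 1) {
    stop("`guess_rate + lapse_rate` must be < 1", call. = FALSE)
  }
  structure(
    list(
      true_logmar = as.numeric(true_logmar),
      slope_sigma = as.numeric(slope_sigma),
      guess_rate = as.numeric(guess_rate),
      lapse_rate = as.numeric(lapse_rate)
    ),
    class = "psychometric_eye"
  )
}

#' Bangerter occlusion filter
#'
#' A translucent foil placed before one eye to degrade acuity, used to
#' simulate amblyopic blur. `blur_shift` is the acuity decrement the foil
#' adds to the eye's true threshold; the nominal density label need not (and
#' in practice does not) predict the measured blur, so the shift is stored
#' explicitly. `inhomogeneity_sd` models the foil's optical non-uniformity:
#' a session-level jitter on the effective threshold, drawn once per test
#' session (not per trial) by the session runner.
#'
#' @param density_label Nominal designation, one of `"<0.1"`, `"0.1"` ...
#'   `"1.0"`.
#' @param blur_shift Acuity decrement in logMAR (>= 0) added to the eye's
#'   threshold.
#' @param inhomogeneity_sd Session-to-session threshold jitter SD (logMAR,
#'   >= 0). Default 0.05.
#' @return An object of class `bangerter_filter`.
#' @export
bangerter_filter <- function(density_label, blur_shift, inhomogeneity_sd = 0.05) {
  labels <- bangerter_labels()
  density_label <- as.character(density_label)
  if (!density_label %in% labels) {
    stop("unknown filter label: ", density_label, call. = FALSE)
  }
  stopifnot(
    is.numeric(blur_shift), length(blur_shift) == 1, blur_shift >= 0,
    is.numeric(inhomogeneity_sd), inhomogeneity_sd >= 0
  )
  structure(
    list(
      density_label = density_label,
      blur_shift = as.numeric(blur_shift),
      inhomogeneity_sd = as.numeric(inhomogeneity_sd)
    ),
    class = "bangerter_filter"
  )
}

#' Nominal Bangerter filter ladder labels, weakest to strongest
#' @return Character vector of density labels.
#' @export
bangerter_labels <- function() {
  c("1.0", "0.9", "0.8", "0.6", "0.4", "0.3", "0.2", "0.1", "<0.1")
}

#' Nominal label -> blur-shift map
#'
#' Stand-in calibration: no quantitative foil calibration is available, so
#' the default map is linear in the label's nominal decimal acuity,
#' `blur_shift = 1.1 - label` (with `"<0.1"` mapped to 1.1 logMAR). The
#' study pipeline adds per-subject, per-filter jitter on top of this nominal
#' value to reflect how poorly labels predict measured blur.
#'
#' @param labels Character vector of density labels.
#' @return Named numeric vector of nominal blur shifts (logMAR).
#' @export
nominal_blur_shift <- function(labels = bangerter_labels()) {
  dec <- suppressWarnings(as.numeric(labels))
  dec[labels == "<0.1"] <- 0
  if (any(is.na(dec))) stop("unknown filter label(s)", call. = FALSE)
  stats::setNames(1.1 - dec, labels)
}

#' Simulated observer (two eyes plus optional filters)
#'
#' The synthetic stand-in for a study participant: a psychometric model per
#' eye and, optionally, a Bangerter filter per eye. The effective threshold
#' of a filtered eye is `true_logmar + blur_shift + session_jitter`, where
#' the jitter is drawn once per test session by the caller (see
#' [draw_session_jitter()]).
#'
#' @param right_eye,left_eye [psychometric_eye()] objects.
#' @param right_filter,left_filter Optional [bangerter_filter()] objects.
#' @param id Optional observer identifier.
#' @param seed Optional integer recorded for provenance; responses are drawn
#'   from R's ambient RNG stream, so reproducibility comes from seeding that
#'   stream (e.g. `set.seed()` or the study pipeline's config seed).
#' @return An object of class `va_observer`.
#' @export
observer <- function(right_eye, left_eye,
                     right_filter = NULL, left_filter = NULL,
                     id = NA_character_, seed = NA_integer_) {
  stopifnot(
    inherits(right_eye, "psychometric_eye"),
    inherits(left_eye, "psychometric_eye"),
    is.null(right_filter) || inherits(right_filter, "bangerter_filter"),
    is.null(left_filter) || inherits(left_filter, "bangerter_filter")
  )
  structure(
    list(
      right_eye = right_eye, left_eye = left_eye,
      right_filter = right_filter, left_filter = left_filter,
      id = as.character(id), seed = seed
    ),
    class = "va_observer"
  )
}

eye_of <- function(obs, side) {
  side <- match.arg(side, c("right", "left"))
  if (side == "right") obs$right_eye else obs$left_eye
}

filter_of <- function(obs, side) {
  side <- match.arg(side, c("right", "left"))
  if (side == "right") obs$right_filter else obs$left_filter
}

#' Probability of a correct response
#'
#' Guess/lapse-corrected logistic psychometric function of logMAR demand.
#' Strictly increasing in demand for `slope_sigma > 0`; tends to
#' `guess_rate` far below threshold and `1 - lapse_rate` far above.
#'
#' @param eye A [psychometric_eye()].
#' @param demand logMAR demand(s) of the presented letter.
#' @param threshold_shift Additive threshold offset (filter blur plus session
#'   jitter); default 0.
#' @return Probability(ies) of a correct response.
#' @export
p_correct <- function(eye, demand, threshold_shift = 0) {
  stopifnot(inherits(eye, "psychometric_eye"), is.numeric(demand), all(is.finite(demand)))
  thr <- eye$true_logmar + threshold_shift
  g <- eye$guess_rate
  l <- eye$lapse_rate
  if (eye$slope_sigma == 0) {
    f <- as.numeric(demand >= thr - 1e-9)  # tie at threshold counts readable
  } else {
    f <- stats::plogis((demand - thr) / eye$slope_sigma)
  }
  g + (1 - g - l) * f
}

#' Draw one trial response
#'
#' A single Bernoulli draw from [p_correct()] for the given eye of an
#' observer, including the eye's filter blur and the supplied session
#' jitter. Consumes exactly one uniform variate from the ambient RNG stream.
#'
#' @param obs A [observer()].
#' @param side `"right"` or `"left"`.
#' @param demand logMAR demand of the letter.
#' @param session_jitter Session-level threshold offset (logMAR), drawn once
#'   per session via [draw_session_jitter()]. Default 0.
#' @return Logical: was the letter identified correctly?
#' @export
respond <- function(obs, side, demand, session_jitter = 0) {
  stopifnot(inherits(obs, "va_observer"))
  flt <- filter_of(obs, side)
  shift <- session_jitter + if (is.null(flt)) 0 else flt$blur_shift
  stats::runif(1) < p_correct(eye_of(obs, side), demand, shift)
}

#' Draw the session-level threshold jitter for one eye
#'
#' Filter foils are optically inhomogeneous, so the effective blur varies
#' from session to session. One normal draw with the filter's
#' `inhomogeneity_sd` models this; unfiltered eyes get zero jitter. The
#' draw is made once per (eye, protocol, repetition) session and shared by
#' all trials in that session.
#'
#' @inheritParams respond
#' @return Session jitter in logMAR.
#' @export
draw_session_jitter <- function(obs, side) {
  flt <- filter_of(obs, side)
  if (is.null(flt) || flt$inhomogeneity_sd == 0) return(0)
  stats::rnorm(1, 0, flt$inhomogeneity_sd)
}

#' Cohort specification for the synthetic study population
#'
#' Defaults emulate the study population: adults with baseline acuity near
#' -0.09 logMAR per eye (SD 0.15 right, 0.17 left), a six-letter guess rate,
#' half-a-line psychometric spread, and the nominal filter ladder with
#' per-subject calibration jitter (SD 0.1 logMAR) and session inhomogeneity
#' (SD 0.05 logMAR).
#'
#' @param mean_re,mean_le Mean true threshold per eye (logMAR).
#' @param sd_re,sd_le Between-subject SD of true thresholds (logMAR).
#' @param slope_sigma,guess_rate,lapse_rate Psychometric parameters shared by
#'   all simulated eyes; see [psychometric_eye()].
#' @param filter_jitter_sd Per-subject SD of the deviation between a foil's
#'   nominal and realised blur shift (logMAR).
#' @param inhomogeneity_sd Session-level jitter SD passed to each assigned
#'   filter (logMAR).
#' @param blur_map Named numeric vector mapping filter labels to nominal
#'   blur shifts; default [nominal_blur_shift()].
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(mean_re = -0.09, sd_re = 0.15,
                        mean_le = -0.09, sd_le = 0.17,
                        slope_sigma = 0.05, guess_rate = 1 / 6,
                        lapse_rate = 0.01,
                        filter_jitter_sd = 0.1,
                        inhomogeneity_sd = 0.05,
                        blur_map = nominal_blur_shift()) {
  stopifnot(sd_re >= 0, sd_le >= 0, filter_jitter_sd >= 0, inhomogeneity_sd >= 0)
  structure(
    list(
      mean_re = mean_re, sd_re = sd_re, mean_le = mean_le, sd_le = sd_le,
      slope_sigma = slope_sigma, guess_rate = guess_rate,
      lapse_rate = lapse_rate, filter_jitter_sd = filter_jitter_sd,
      inhomogeneity_sd = inhomogeneity_sd, blur_map = blur_map
    ),
    class = "cohort_spec"
  )
}

#' Sample a synthetic cohort with fitted filters
#'
#' Draws per-eye true thresholds from the cohort spec's normal
#' distributions, then runs the screening procedure
#' ([screen_and_fit_filters()]) on each subject so that the better eye's
#' screened acuity lies within the screening window and the interocular
#' difference meets the minimum. Deterministic given `seed`.
#'
#' @param n Number of observers (>= 1).
#' @param spec A [cohort_spec()].
#' @param config A [study_config()] supplying the screening window; its
#'   cohort spec is ignored in favour of `spec`.
#' @param seed Optional integer seed; if supplied, `set.seed(seed)` is called.
#' @return A list of `va_observer` objects with a `screening` attribute
#'   (tibble of per-subject screening records).
#' @export
sample_cohort <- function(n, spec = cohort_spec(), config = study_config(), seed = NULL) {
  if (!is.numeric(n) || length(n) != 1 || n < 1) {
    stop("`n` must be a count >= 1", call. = FALSE)
  }
  n <- as.integer(n)
  if (!is.null(seed)) set.seed(seed)
  if (config$screening_floor >= config$screening_ceiling) {
    stop("empty screening window", call. = FALSE)
  }
  obs <- vector("list", n)
  recs <- vector("list", n)
  for (i in seq_len(n)) {
    re <- psychometric_eye(stats::rnorm(1, spec$mean_re, spec$sd_re),
                           spec$slope_sigma, spec$guess_rate, spec$lapse_rate)
    le <- psychometric_eye(stats::rnorm(1, spec$mean_le, spec$sd_le),
                           spec$slope_sigma, spec$guess_rate, spec$lapse_rate)
    o <- observer(re, le, id = sprintf("S%02d", i))
    fit <- screen_and_fit_filters(o, config, spec)
    obs[[i]] <- fit$observer
    recs[[i]] <- fit$record
  }
  attr(obs, "screening") <- dplyr::bind_rows(recs)
  obs
}
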