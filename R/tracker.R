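#' @title Distance-staircase test (tracker protocol)
#'
#' @description A fixed-size optotype is shown on the phone while the tester
#' moves it along a logarithmic distance grid (one grid step = one logMAR
#' line). The staircase has two phases:
#'
#' * **coarse** ("three up, one down"): one letter per distance; a correct
#'   answer moves the phone three lines farther (harder by distance, easier
#'   by angle is reversed here: farther = lower logMAR demand), clamped at
#'   the reference distance; the first wrong answer switches to the fine
#'   phase one line closer.
#' * **fine**: blocks of up to five letters at each distance, pass on three
#'   correct, fail on three incorrect; a failed block moves one line closer;
#'   the first passed block ends the test at that distance.
#'
#' A correct single letter at the farthest grid distance ends the test at the
#' best possible score; failing the block at the closest grid distance ends
#' it with a below-floor sentinel (acuity worse than the worst grid line).
#'
#' @name tracker_protocol
NULL

FLOOR_SENTINEL <- -1L  # final level code: worse than the closest grid line

new_staircase_state <- function(scale, level) {
  n <- length(grid_logmars(scale))
  structure(
    list(
      scale = scale,
      n_levels = n,
      level = level,              # 0-based grid index; 0 = reference distance
      phase = "coarse",
      block_correct = 0L,
      block_incorrect = 0L,
      finished = FALSE,
      final_level = NA_integer_,  # grid index, or FLOOR_SENTINEL
      log = list()
    ),
    class = "staircase_state"
  )
}

state_level_logmar <- function(state, level = state$level) {
  state$scale$reference_logmar + state$scale$line_step * level
}

state_level_distance <- function(state, level = state$level) {
  logmar_to_distance(state_level_logmar(state, level), state$scale)
}

#' Start a tracker staircase
#'
#' @param scale An [acuity_scale()].
#' @param start_distance_cm Starting distance; must be a grid distance
#'   (default 30 cm, the 1.0 logMAR line for the default scale).
#' @param snap_start If `TRUE`, an off-grid start is snapped to the nearest
#'   grid distance instead of raising an error.
#' @return A `staircase_state` in the coarse phase.
#' @export
tracker_start <- function(scale = acuity_scale(), start_distance_cm = 30,
                          snap_start = FALSE) {
  stopifnot(inherits(scale, "acuity_scale"),
            is.numeric(start_distance_cm), start_distance_cm > 0)
  dists <- grid_distances(scale)
  rel <- abs(dists - start_distance_cm) / start_distance_cm
  if (min(rel) > 1e-6) {
    if (!snap_start) {
      stop(sprintf("start distance %.6g cm is not on the grid (use snap_start = TRUE to snap)",
                   start_distance_cm), call. = FALSE)
    }
  }
  level <- which.min(abs(dists - start_distance_cm)) - 1L
  new_staircase_state(scale, level)
}

#' Current instruction for the tester
#'
#' Pure read of the staircase state: the distance (cm) at which to hold the
#' phone and how many letters remain in the current block (5 in the coarse
#' phase, where at most one is actually used before the distance changes).
#'
#' @param state A `staircase_state`.
#' @return List with `distance_cm` and `letters_remaining`.
#' @export
next_instruction <- function(state) {
  stopifnot(inherits(state, "staircase_state"))
  if (state$finished) stop("test already finished", call. = FALSE)
  list(
    distance_cm = state_level_distance(state),
    letters_remaining = 5L - (state$block_correct + state$block_incorrect)
  )
}

#' Record one response and advance the staircase
#'
#' Applies the staircase transition rules (see [tracker_protocol]) and
#' appends the trial to the log.
#'
#' @param state A `staircase_state` (not finished).
#' @param correct Logical: was the letter identified correctly?
#' @return The updated `staircase_state`.
#' @export
record_response <- function(state, correct) {
  stopifnot(inherits(state, "staircase_state"), is.logical(correct), length(correct) == 1)
  if (state$finished) stop("test already finished", call. = FALSE)
  state$log[[length(state$log) + 1L]] <- list(
    phase = state$phase,
    distance_cm = state_level_distance(state),
    demand_logmar = state_level_logmar(state),
    correct = correct
  )
  max_level <- state$n_levels - 1L
  if (state$phase == "coarse") {
    if (correct) {
      if (state$level == 0L) {
        state$finished <- TRUE
        state$final_level <- 0L
      } else {
        state$level <- max(0L, state$level - 3L)
      }
    } else {
      state$phase <- "fine"
      state$level <- min(max_level, state$level + 1L)
      state$block_correct <- 0L
      state$block_incorrect <- 0L
    }
  } else {
    if (correct) state$block_correct <- state$block_correct + 1L
    else state$block_incorrect <- state$block_incorrect + 1L
    if (state$block_correct == 3L) {
      state$finished <- TRUE
      state$final_level <- state$level
    } else if (state$block_incorrect == 3L) {
      if (state$level == max_level) {
        state$finished <- TRUE
        state$final_level <- FLOOR_SENTINEL
      } else {
        state$level <- state$level + 1L
        state$block_correct <- 0L
        state$block_incorrect <- 0L
      }
    }
  }
  state
}

staircase_log_tibble <- function(state) {
  if (length(state$log) == 0) {
    return(tibble::tibble(trial = integer(), phase = character(),
                          distance_cm = numeric(), demand_logmar = numeric(),
                          correct = logical()))
  }
  tibble::tibble(
    trial = seq_along(state$log),
    phase = vapply(state$log, `[[`, character(1), "phase"),
    distance_cm = vapply(state$log, `[[`, numeric(1), "distance_cm"),
    demand_logmar = vapply(state$log, `[[`, numeric(1), "demand_logmar"),
    correct = vapply(state$log, `[[`, logical(1), "correct")
  )
}

new_test_result <- function(protocol, eye, logmar, sentinel, final_distance_cm, trials) {
  structure(
    list(protocol = protocol, eye = eye, logmar = logmar, sentinel = sentinel,
         final_distance_cm = final_distance_cm, trials = trials),
    class = "va_test_result"
  )
}

#' @export
print.va_test_result <- function(x, ...) {
  score <- if (x$sentinel == "none") sprintf("%.2f logMAR", x$logmar)
           else sprintf("<%s sentinel>", x$sentinel)
  cat(sprintf("<va_test_result> %s, %s eye: %s (%d trials)\n",
              x$protocol, x$eye, score, nrow(x$trials)))
  invisible(x)
}

#' Run a full tracker test on a simulated observer
#'
#' Drives [record_response()] with [respond()] draws until the staircase
#' finishes.
#'
#' @inheritParams respond
#' @param scale An [acuity_scale()].
#' @param start_distance_cm Starting distance (grid point), default 30 cm.
#' @return A `va_test_result`: `logmar` is the demand of the final distance
#'   (NA with `sentinel = "floor"` when the closest-distance block was
#'   failed), `final_distance_cm` the final grid distance, `trials` the
#'   trial log.
#' @export
run_tracker_test <- function(obs, side, scale = acuity_scale(),
                             start_distance_cm = 30, session_jitter = 0) {
  side <- match.arg(side, c("right", "left"))
  state <- tracker_start(scale, start_distance_cm)
  while (!state$finished) {
    demand <- state_level_logmar(state)
    state <- record_response(state, respond(obs, side, demand, session_jitter))
  }
  if (state$final_level == FLOOR_SENTINEL) {
    new_test_result("tracker", side, NA_real_, "floor", NA_real_,
                    staircase_log_tibble(state))
  } else {
    new_test_result("tracker", side,
                    state_level_logmar(state, state$final_level), "none",
                    state_level_distance(state, state$final_level),
                    staircase_log_tibble(state))
  }
}

#' Starting distance based on a previous result
#'
#' The app shortens retests by starting where the previous test finished.
#' A floor-sentinel previous result falls back to the default 30 cm start.
#'
#' @param previous A finished tracker `va_test_result`.
#' @param default_start_cm Fallback start distance. Default 30.
#' @return Start distance in cm.
#' @export
previous_result_start <- function(previous, default_start_cm = 30) {
  stopifnot(inherits(previous, "va_test_result"))
  if (previous$sentinel != "none" || is.na(previous$final_distance_cm)) {
    return(default_start_cm)
  }
  previous$final_distance_cm
}

#' Serialize / restore a staircase state (pause and resume)
#'
#' @param state A `staircase_state`.
#' @return `staircase_state_to_json()`: a JSON string;
#'   `staircase_state_from_json()`: the restored state.
#' @export
staircase_state_to_json <- function(state) {
  stopifnot(inherits(state, "staircase_state"))
  jsonlite::toJSON(
    list(
      scale = unclass(state$scale),
      level = state$level, phase = state$phase,
      block_correct = state$block_correct,
      block_incorrect = state$block_incorrect,
      finished = state$finished, final_level = state$final_level,
      log = state$log
    ),
    auto_unbox = TRUE, digits = NA, null = "null", na = "null"
  )
}

#' @rdname staircase_state_to_json
#' @param json JSON string produced by `staircase_state_to_json()`.
#' @export
staircase_state_from_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyDataFrame = FALSE)
  scale <- do.call(acuity_scale, x$scale)
  state <- new_staircase_state(scale, as.integer(x$level))
  state$phase <- x$phase
  state$block_correct <- as.integer(x$block_correct)
  state$block_incorrect <- as.integer(x$block_incorrect)
  state$finished <- isTRUE(x$finished)
  state$final_level <- if (is.null(x$final_level) || is.na(x$final_level)) {
    NA_integer_
  } else {
    as.integer(x$final_level)
  }
  state$log <- lapply(x$log, function(r) {
    list(phase = r$phase, distance_cm = as.numeric(r$distance_cm),
         demand_logmar = as.numeric(r$demand_logmar), correct = isTRUE(r$correct))
  })
  state
}
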