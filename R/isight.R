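#' @title Letter-size threshold test (iSight protocol)
#'
#' @description A single crowded letter is shown at a fixed viewing position
#' while its size steps through logMAR lines from 0.7 down to 0.0:
#'
#' 1. descend one letter per line from 0.7 logMAR until a letter is missed;
#' 2. return to the line above and test four more letters there (the letter
#'    already answered correctly counts as one of the five);
#' 3. if at least 3/5 are correct, continue downward testing five letters
#'    per line;
#' 4. stop at the first line scoring under 3/5;
#' 5. the score is the deepest line with at least 3/5 correct (scores are
#'    line-rounded; raw letter counts stay in the trial log);
#' 6. a miss on the very first letter at 0.7 yields an above-ceiling
#'    sentinel (acuity worse than the chart can display).
#'
#' If the block on the "line above" itself scores under 3/5 the protocol
#' keeps moving up a line at a time (again crediting the descend-phase
#' correct letter) until a block passes, so the score is always the deepest
#' line with a passed block. Each line is blocked at most once: a pass
#' directly above an already-failed line ends the test at the passing line.
#' Blocks stop early at three correct or three incorrect.
#'
#' @name isight_protocol
NULL

#' Pass/fail score for one line
#'
#' A line passes when at least three of its five letters are identified
#' correctly. Early-stopped blocks (three correct or three incorrect seen)
#' may present fewer than five flags.
#'
#' @param trials_on_line Logical vector of 1--5 correct flags.
#' @return `TRUE` if the line passes.
#' @export
line_score <- function(trials_on_line) {
  stopifnot(is.logical(trials_on_line))
  if (length(trials_on_line) < 1 || length(trials_on_line) > 5) {
    stop("a line holds 1 to 5 letters", call. = FALSE)
  }
  sum(trials_on_line) >= 3
}

# Run one confirm block at `line`, with `credit` letters already correct
# (the descend-phase letter). Returns pass flag and appends to log.
isight_block <- function(obs, side, line, credit, session_jitter, log) {
  n_correct <- credit
  n_incorrect <- 0L
  while (n_correct < 3L && n_incorrect < 3L) {
    ok <- respond(obs, side, line, session_jitter)
    log[[length(log) + 1L]] <- list(phase = "confirm", line_logmar = line,
                                    correct = ok)
    if (ok) n_correct <- n_correct + 1L else n_incorrect <- n_incorrect + 1L
  }
  list(pass = n_correct >= 3L, log = log,
       n_correct = n_correct, n_incorrect = n_incorrect)
}

#' Run a full iSight test on a simulated observer
#'
#' @inheritParams respond
#' @param top_line Largest (easiest by size) line on the chart, logMAR.
#'   Default 0.7, the display limit of the phone.
#' @param bottom_line Smallest line, logMAR. Default 0.0.
#' @param line_step One line in logMAR. Default 0.1.
#' @param fresh_block_letters If `TRUE`, the confirm block on the line above
#'   an error shows five fresh letters instead of crediting the letter
#'   already answered there. Default `FALSE` (the app's "test 4 more
#'   letters" behaviour).
#' @return A `va_test_result` with `logmar` the line-rounded score in
#'   `{bottom_line, ..., top_line}`, or NA with `sentinel = "ceiling"` when
#'   acuity is worse than the chart range.
#' @export
run_isight_test <- function(obs, side, top_line = 0.7, bottom_line = 0,
                            line_step = 0.1, session_jitter = 0,
                            fresh_block_letters = FALSE) {
  side <- match.arg(side, c("right", "left"))
  stopifnot(top_line >= bottom_line, line_step > 0)
  lines <- round(seq(top_line, bottom_line, by = -line_step), 10)
  log <- list()
  eps <- 1e-9

  finish <- function(logmar, sentinel) {
    trials <- if (length(log) == 0) {
      tibble::tibble(trial = integer(), phase = character(),
                     line_logmar = numeric(), correct = logical())
    } else {
      tibble::tibble(
        trial = seq_along(log),
        phase = vapply(log, `[[`, character(1), "phase"),
        line_logmar = vapply(log, `[[`, numeric(1), "line_logmar"),
        correct = vapply(log, `[[`, logical(1), "correct")
      )
    }
    new_test_result("isight", side, logmar, sentinel, NA_real_, trials)
  }

  # Descend phase: one letter per line until the first error.
  error_line <- NA_real_
  for (ln in lines) {
    ok <- respond(obs, side, ln, session_jitter)
    log[[length(log) + 1L]] <- list(phase = "descend", line_logmar = ln,
                                    correct = ok)
    if (!ok) { error_line <- ln; break }
  }

  if (!is.na(error_line) && abs(error_line - top_line) < eps) {
    return(finish(NA_real_, "ceiling"))  # missed the first letter at the top
  }

  # Confirm phase starts one line above the error (crediting the descend
  # letter), or on the bottom line if the descent never erred.
  if (is.na(error_line)) {
    current <- bottom_line
  } else {
    current <- round(error_line + line_step, 10)
  }
  credit <- 1L  # descend answered this line correctly
  passed_line <- NA_real_
  failed_lines <- numeric(0)

  repeat {
    blk <- isight_block(obs, side, current, credit, session_jitter, log)
    log <- blk$log
    if (blk$pass) {
      passed_line <- current
      # each line gets at most one block: a pass directly above an already
      # failed line is the deepest achievable score
      below <- round(current - line_step, 10)
      if (current <= bottom_line + eps ||
          any(abs(failed_lines - below) < eps)) {
        return(finish(current, "none"))
      }
      current <- below
      credit <- 0L
    } else {
      failed_lines <- c(failed_lines, current)
      if (!is.na(passed_line)) return(finish(passed_line, "none"))
      if (current >= top_line - eps) return(finish(NA_real_, "ceiling"))
      current <- round(current + line_step, 10)
      credit <- if (fresh_block_letters) 0L else 1L
    }
  }
}
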