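# Deterministic step observer: reads any letter whose demand is at or above
# its threshold, never guesses, never lapses.
step_observer <- function(thr_right, thr_left = thr_right) {
  observer(
    psychometric_eye(thr_right, slope_sigma = 0, guess_rate = 0, lapse_rate = 0),
    psychometric_eye(thr_left, slope_sigma = 0, guess_rate = 0, lapse_rate = 0)
  )
}

# Brute-force tracker simulator written straight from the testing protocol
# prose, independent of the staircase state machine. Consumes the response
# bits in order; returns where it got to when they ran out.
#   responses : logical vector
#   start_level: 0-based grid index (0 = farthest distance)
# Returns list(done, final) where final is a grid index or "floor", or
# list(done = FALSE, level, phase) if responses were exhausted.
oracle_tracker <- function(responses, n_levels = 14, start_level = 10) {
  i <- start_level
  k <- 1
  # Coarse: one letter per distance; correct -> three lines farther
  # (clamped); incorrect -> one line closer, start the fine blocks.
  repeat {
    if (k > length(responses)) {
      return(list(done = FALSE, level = i, phase = "coarse"))
    }
    r <- responses[k]; k <- k + 1
    if (r) {
      if (i == 0) return(list(done = TRUE, final = 0))
      i <- max(0, i - 3)
    } else {
      i <- min(n_levels - 1, i + 1)
      break
    }
  }
  # Fine: five-letter blocks, pass at 3 correct, fail at 3 incorrect.
  repeat {
    cc <- 0; ci <- 0
    repeat {
      if (k > length(responses)) {
        return(list(done = FALSE, level = i, phase = "fine"))
      }
      r <- responses[k]; k <- k + 1
      if (r) cc <- cc + 1 else ci <- ci + 1
      if (cc == 3) return(list(done = TRUE, final = i))
      if (ci == 3) break
    }
    if (i == n_levels - 1) return(list(done = TRUE, final = "floor"))
    i <- i + 1
  }
}

# Drive the package's state machine with a fixed response vector; mirror
# oracle_tracker's return shape.
machine_tracker <- function(responses, scale = acuity_scale(),
                            start_distance_cm = 30) {
  state <- tracker_start(scale, start_distance_cm)
  for (r in responses) {
    if (state$finished) break
    state <- record_response(state, r)
  }
  if (state$finished) {
    final <- if (state$final_level < 0) "floor" else state$final_level
    list(done = TRUE, final = final)
  } else {
    list(done = FALSE, level = state$level, phase = state$phase)
  }
}

# Deepest line with a >= 3/5 block, for a deterministic step observer on the
# letter-size chart: the smallest line demand at or above the threshold
# (ceiling to the grid), or ceiling-sentinel if even the top line is below
# threshold.
expected_isight_score <- function(threshold, top = 0.7, bottom = 0, step = 0.1) {
  if (threshold > top + 1e-9) return(NA_real_)
  lines <- round(seq(bottom, top, by = step), 10)
  readable <- lines[lines >= threshold - 1e-9]
  min(readable)
}
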