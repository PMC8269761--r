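test_that("staircase starts at 30 cm in the coarse phase", {
  st <- tracker_start()
  expect_equal(st$phase, "coarse")
  expect_false(st$finished)
  ins <- next_instruction(st)
  expect_equal(ins$distance_cm, 30, tolerance = 1e-9)
  expect_equal(ins$letters_remaining, 5L)
  st300 <- tracker_start(start_distance_cm = 300)
  expect_equal(st300$level, 0L)
  expect_error(tracker_start(start_distance_cm = 29), "grid")
  snapped <- tracker_start(start_distance_cm = 29, snap_start = TRUE)
  expect_equal(next_instruction(snapped)$distance_cm, 30, tolerance = 1e-9)
})

test_that("coarse-phase moves jump three lines and clamp at the far end", {
  st <- tracker_start()                     # level 10 = 1.0 logMAR
  st <- record_response(st, TRUE)
  expect_equal(st$level, 7L)                # 0.7 logMAR
  expect_equal(next_instruction(st)$distance_cm, 300 * 10^-0.7, tolerance = 1e-9)
  st <- record_response(st, TRUE)           # -> 0.4
  st <- record_response(st, TRUE)           # -> 0.1
  st <- record_response(st, TRUE)           # clamp -> 0.0
  expect_equal(st$level, 0L)
  st <- record_response(st, TRUE)           # correct at ceiling ends the test
  expect_true(st$finished)
  expect_equal(st$final_level, 0L)
})

test_that("a coarse miss opens the fine phase one line closer", {
  st <- tracker_start()
  st <- record_response(st, FALSE)
  expect_equal(st$phase, "fine")
  expect_equal(st$level, 11L)
  expect_equal(st$block_correct + st$block_incorrect, 0L)
})

test_that("fine blocks stop early at three correct or three incorrect", {
  st <- tracker_start()
  st <- record_response(st, FALSE)          # fine at level 11
  for (r in c(TRUE, TRUE, TRUE)) st <- record_response(st, r)
  expect_true(st$finished)
  expect_equal(st$final_level, 11L)

  st <- tracker_start()
  st <- record_response(st, FALSE)          # fine at level 11
  lvl <- st$level
  for (r in c(FALSE, TRUE, FALSE, FALSE)) st <- record_response(st, r)
  expect_false(st$finished)                 # block failed after 4 letters
  expect_equal(st$level, lvl + 1L)
  expect_error(record_response(record_response(record_response(
    record_response(tracker_start(), FALSE), TRUE), TRUE), TRUE) |>
      record_response(TRUE), "finished")
})

test_that("failing the block at the closest distance yields the floor sentinel", {
  o <- step_observer(2.0)                   # cannot read anything on the grid
  res <- run_tracker_test(o, "right")
  expect_equal(res$sentinel, "floor")
  expect_true(is.na(res$logmar))
  expect_true(is.na(res$final_distance_cm))
})

test_that("deterministic observers are scored at their threshold line", {
  res <- run_tracker_test(step_observer(0.7), "right")
  expect_equal(res$logmar, 0.7, tolerance = 1e-12)
  expect_equal(res$final_distance_cm, 300 * 10^-0.7, tolerance = 1e-9)
  perfect <- step_observer(-10)
  res0 <- run_tracker_test(perfect, "right")
  expect_equal(res0$logmar, 0)
  expect_equal(res0$final_distance_cm, 300)
  # trial log is complete and consistent
  expect_equal(nrow(res$trials), sum(res$trials$correct) + sum(!res$trials$correct))
  expect_true(all(res$trials$demand_logmar %in% seq(0, 1.3, by = 0.1) |
                    abs(res$trials$demand_logmar -
                          round(res$trials$demand_logmar, 1)) < 1e-9))
})

test_that("state machine matches the literal-prose simulator on all 12-letter patterns", {
  n_bits <- 12
  norm <- function(x) {
    x[] <- lapply(x, function(v) if (is.numeric(v)) as.numeric(v) else v)
    x[order(names(x))]
  }
  mismatches <- 0L
  for (code in 0:(2^n_bits - 1)) {
    bits <- as.logical(bitwAnd(bitwShiftR(code, 0:(n_bits - 1)), 1L))
    a <- norm(machine_tracker(bits))
    b <- norm(oracle_tracker(bits))
    if (!identical(a, b)) mismatches <- mismatches + 1L
  }
  expect_identical(mismatches, 0L)
})

test_that("every response pattern terminates within the trial bound", {
  set.seed(99)
  n_levels <- 14
  bound <- 5 + 5 * n_levels
  for (i in 1:200) {
    st <- tracker_start()
    trials <- 0
    while (!st$finished && trials <= bound) {
      st <- record_response(st, runif(1) < 0.5)
      trials <- trials + 1
    }
    expect_true(st$finished)
    expect_lte(trials, bound)
  }
})

test_that("scores land on the grid or the floor sentinel", {
  set.seed(5)
  o <- observer(psychometric_eye(0.5), psychometric_eye(0.5))
  grid <- seq(0, 1.3, by = 0.1)
  for (i in 1:50) {
    res <- run_tracker_test(o, "right")
    if (res$sentinel == "none") {
      expect_true(min(abs(res$logmar - grid)) < 1e-9)
    } else {
      expect_equal(res$sentinel, "floor")
    }
  }
})

test_that("retests start where the previous test finished", {
  res <- run_tracker_test(step_observer(0.7), "right")
  expect_equal(previous_result_start(res), res$final_distance_cm)
  floored <- run_tracker_test(step_observer(5), "right")
  expect_equal(previous_result_start(floored), 30)
  res300 <- run_tracker_test(step_observer(-1), "right")
  expect_equal(previous_result_start(res300), 300)
  # and the restart distance is accepted as a grid start
  res2 <- run_tracker_test(step_observer(0.7), "right",
                           start_distance_cm = previous_result_start(res))
  expect_equal(res2$logmar, 0.7, tolerance = 1e-12)
})

test_that("staircase state serialises to JSON and back", {
  st <- tracker_start()
  st <- record_response(st, TRUE)
  st <- record_response(st, FALSE)
  st <- record_response(st, TRUE)
  rt <- staircase_state_from_json(staircase_state_to_json(st))
  expect_equal(rt$level, st$level)
  expect_equal(rt$phase, st$phase)
  expect_equal(rt$block_correct, st$block_correct)
  expect_equal(rt$log, st$log)
  # resumed state continues identically
  a <- record_response(st, TRUE)
  b <- record_response(rt, TRUE)
  expect_equal(b$level, a$level)
  expect_equal(b$finished, a$finished)
})
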