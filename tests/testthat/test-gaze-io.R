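test_that("gaze files round-trip byte-identically through the dialect", {
  smp <- data.frame(participant_id = "P0001", trial_id = 1L,
                    timestamp_ms = c(0, 4, 8),
                    gaze_x_px = c(960.5, 961, NA),
                    gaze_y_px = c(540, 540.25, NA),
                    pupil_left_mm = c(3.5, NA, 3.6),
                    pupil_right_mm = c(3.4, 3.5, 3.6),
                    valid_left = c(1L, 0L, 1L), valid_right = c(1L, 1L, 1L))
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_gaze_file(smp, f1)
  back <- read_gaze_file(f1)
  expect_equal(nrow(back), 3)
  write_gaze_file(back, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  unlink(c(f1, f2))
})

test_that("malformed gaze files fail with located format errors", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("participant_id,bogus", "P1,1"), f)
  expect_error(read_gaze_file(f), "format error")
  smp <- data.frame(participant_id = "P1", trial_id = 1L,
                    timestamp_ms = c(0, 10, 5),
                    gaze_x_px = 1, gaze_y_px = 1, pupil_left_mm = 3,
                    pupil_right_mm = 3, valid_left = 1L, valid_right = 1L)
  write_gaze_file(smp, f)
  expect_error(read_gaze_file(f), "nonmonotone")
  writeLines("participant_id,trial_id,timestamp_ms,gaze_x_px,gaze_y_px,pupil_left_mm,pupil_right_mm,valid_left,valid_right", f)
  expect_error(read_gaze_file(f), "empty")
  unlink(f)
})

test_that("validity fraction and the >80% inclusion rule", {
  mk <- function(n_valid, n) {
    data.frame(valid_left = rep(c(1L, 0L), c(n_valid, n - n_valid)),
               valid_right = rep(0L, n))
  }
  expect_equal(validity_fraction(mk(100, 100)), 1)
  expect_true(include_participant(validity_fraction(mk(100, 100))))
  expect_equal(validity_fraction(mk(79, 100)), 0.79)
  expect_false(include_participant(0.79))
  expect_equal(validity_fraction(mk(81, 100)), 0.81)
  expect_true(include_participant(0.81))
  expect_false(include_participant(0.8))  # strictly greater than
  expect_error(validity_fraction(mk(0, 0)[0, ]), "empty")
})

test_that("I-VT resolves a clean step trajectory into 2 fixations, 1 saccade", {
  scr <- default_screen()
  smp <- make_step_stream(to_deg = 10, t_jump = 500, jump_ms = 20,
                          t_end = 1000)
  ev <- detect_events(smp, scr)
  expect_equal(nrow(ev$fixations), 2)
  expect_equal(nrow(ev$saccades), 1)
  expect_equal(ev$saccades$amplitude, 10, tolerance = 0.15)
  # detected boundaries within 2 samples (8 ms) of the true jump window
  expect_lt(abs(ev$saccades$t_start - 500), 2 * 4 + 1e-9)
  expect_lt(abs(ev$saccades$t_end - 520), 2 * 4 + 1e-9)
  expect_gte(ev$saccades$peak_velocity, ev$saccades$mean_velocity)
})

test_that("perfectly still gaze yields a single fixation and no saccades", {
  scr <- default_screen()
  smp <- make_step_stream(to_deg = 0, t_end = 1000)
  ev <- detect_events(smp, scr)
  expect_equal(nrow(ev$fixations), 1)
  expect_equal(nrow(ev$saccades), 0)
  expect_equal(ev$fixations$x, 960, tolerance = 1e-6)
})

test_that("gaps split fixations only beyond the bridging limit", {
  scr <- default_screen()
  smp <- make_step_stream(to_deg = 0, t_end = 1000)
  # 40 ms hole (< 75 ms): bridged into one fixation
  hole <- smp$timestamp_ms > 480 & smp$timestamp_ms < 520
  ev1 <- detect_events(smp[!hole, ], scr)
  expect_equal(nrow(ev1$fixations), 1)
  # 200 ms hole: the fixation splits
  hole2 <- smp$timestamp_ms > 400 & smp$timestamp_ms < 600
  ev2 <- detect_events(smp[!hole2, ], scr)
  expect_equal(nrow(ev2$fixations), 2)
})

test_that("an all-invalid stream warns and returns no events", {
  scr <- default_screen()
  smp <- make_step_stream(t_end = 200)
  smp$valid_left <- 0L; smp$valid_right <- 0L
  expect_warning(ev <- detect_events(smp, scr), "valid")
  expect_equal(nrow(ev$fixations) + nrow(ev$saccades), 0)
})

test_that("fixation and saccade spans never overlap on synthetic cohorts", {
  set.seed(5)
  scr <- default_screen()
  ph <- phenotype_params("ADHD-like")
  for (task in c("prosaccade", "antisaccade", "delayed")) {
    g <- generate_trial(ph, trial_spec(task, 15, "left"), scr, 250)
    ev <- detect_events(g$samples, scr)
    spans <- rbind(ev$fixations[, c("t_start", "t_end")],
                   ev$saccades[, c("t_start", "t_end")])
    spans <- spans[order(spans$t_start), ]
    if (nrow(spans) > 1) {
      expect_true(all(spans$t_start[-1] >= spans$t_end[-nrow(spans)] - 1e-9))
    }
  }
})

test_that("trial segmentation yields one record per marker", {
  set.seed(9)
  co <- generate_cohort(cohort_config(n_td = 1, n_adhd = 1, seed = 9))
  one <- co$markers$participant_id == co$markers$participant_id[1]
  expect_equal(sum(one), 36)
  recs <- segment_trials(co$gaze[co$gaze$participant_id ==
                                   co$markers$participant_id[1], ],
                         co$markers[one, ], default_screen(),
                         detect = FALSE)
  expect_length(recs, 36)
  expect_false(any(vapply(recs, `[[`, TRUE, "incomplete")))
  # samples were re-based to the trial onset
  expect_true(all(vapply(recs, function(r) min(r$samples$timestamp_ms), 0) <
                    1))
  # a marker with no samples is flagged incomplete
  mk2 <- co$markers
  mk2$trial_id[1] <- 999L
  recs2 <- segment_trials(co$gaze, mk2[1, ], default_screen(),
                          detect = FALSE)
  expect_true(recs2[[1]]$incomplete)
})
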