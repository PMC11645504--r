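# Shared fixture builders. Everything is generated in code; no data files.

default_screen <- function(rate = 250) screen_config(sampling_rate_hz = rate)

# noise-free gaze stream: still at `from` until t_jump, a minimum-jerk step
# to `to` lasting jump_ms, then still until t_end; timestamps in ms
make_step_stream <- function(from = c(960, 540), to_deg = 10,
                             t_jump = 500, jump_ms = 20, t_end = 1000,
                             rate = 250, screen = default_screen(rate)) {
  off_px <- eccentricity_to_px(to_deg, screen)
  to <- from + c(off_px, 0)
  ts <- seq(0, t_end, by = 1000 / rate)
  s <- pmin(pmax((ts - t_jump) / jump_ms, 0), 1)
  s <- 10 * s^3 - 15 * s^4 + 6 * s^5
  data.frame(timestamp_ms = ts,
             gaze_x_px = from[1] + s * (to[1] - from[1]),
             gaze_y_px = from[2] + s * (to[2] - from[2]),
             pupil_left_mm = 4, pupil_right_mm = 4,
             valid_left = 1L, valid_right = 1L)
}

make_fixations <- function(x, y, t_start, duration = 200) {
  data.frame(t_start = t_start, t_end = t_start + duration,
             duration = rep_len(duration, length(x)), x = x, y = y)
}

# tiny trial-level biomarker table for aggregation tests
make_trials_df <- function(pid = "P1", task = "prosaccade", ecc = 7,
                           n = 4, values = list()) {
  df <- data.frame(participant_id = pid, trial_id = seq_len(n),
                   task = task, eccentricity_deg = ecc,
                   side = rep_len(c("left", "right"), n),
                   order = rep(c(1L, 2L), each = ceiling(n / 2))[seq_len(n)],
                   stringsAsFactors = FALSE)
  for (m in biomarker_catalog()$metric) df[[m]] <- NA_real_
  for (nm in names(values)) df[[nm]] <- values[[nm]]
  df
}

# cached mid-size synthetic cohort shared by the end-to-end acceptance checks
.cohort_cache <- new.env(parent = emptyenv())

acceptance_cohort <- function() {
  if (is.null(.cohort_cache$ft)) {
    co <- generate_cohort(cohort_config(n_td = 50, n_adhd = 50, seed = 20240501))
    scr <- screen_config(sampling_rate_hz = 250)
    bm <- extract_biomarkers(co$gaze, co$markers, scr)
    .cohort_cache$ft <- aggregate_participants(bm, co$participants)
    .cohort_cache$biomarkers <- bm
    .cohort_cache$participants <- co$participants
  }
  .cohort_cache
}
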