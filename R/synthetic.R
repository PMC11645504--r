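#' Behavioral phenotype parameters for the gaze simulator
#'
#' Parameter set driving the synthetic gaze generator for one group. The two
#' presets encode the qualitative group contrasts reported for children with
#' ADHD relative to typically developing (TD) children: longer saccade
#' latency, more direction errors and search behavior in the antisaccade
#' task, more fixations on unrelated areas, more intrusive saccades and
#' wrong-period target fixations in the delayed task, lower completion rates,
#' slower saccades, larger pupil-diameter fluctuation, and more spatially
#' dispersed fixations. Magnitudes are simulator choices (the directions, not
#' the sizes, are the modeled quantity).
#'
#' @param preset `"TD-like"` or `"ADHD-like"`.
#' @param ... named overrides of individual parameters.
#' @return A list of class `phenotype_params`.
#' @export
phenotype_params <- function(preset = c("TD-like", "ADHD-like"), ...) {
  preset <- match.arg(preset)
  p <- if (preset == "TD-like") {
    list(latency_mean_ms = 200, latency_sd_ms = 40,
         direction_error_prob = 0.10,
         search_prob = 0.15, search_n_mean = 2,
         ua_fix_rate = 0.3,
         intrusive_prob = 0.10,
         ta_wrong_prob = 0.15,
         completion_prob = 0.97,
         peak_velocity_mean = 450, peak_velocity_sd = 40,
         pupil_baseline_mm = 4.0, pupil_sd_mm = 0.15, pupil_noise_mm = 0.02,
         fix_jitter_px = 15, gaze_noise_px = 3,
         artifact_rate = 1, blink_rate = 0.3)
  } else {
    list(latency_mean_ms = 350, latency_sd_ms = 80,
         direction_error_prob = 0.45,
         search_prob = 0.55, search_n_mean = 3,
         ua_fix_rate = 1.5,
         intrusive_prob = 0.50,
         ta_wrong_prob = 0.50,
         completion_prob = 0.85,
         peak_velocity_mean = 360, peak_velocity_sd = 40,
         pupil_baseline_mm = 4.1, pupil_sd_mm = 0.35, pupil_noise_mm = 0.03,
         fix_jitter_px = 30, gaze_noise_px = 6,
         artifact_rate = 2, blink_rate = 0.5)
  }
  over <- list(...)
  bad <- setdiff(names(over), names(p))
  if (length(bad)) stop("unknown phenotype parameters: ",
                        paste(bad, collapse = ", "))
  p[names(over)] <- over
  probs <- c("direction_error_prob", "search_prob", "intrusive_prob",
             "ta_wrong_prob", "completion_prob")
  if (any(unlist(p[probs]) < 0 | unlist(p[probs]) > 1)) {
    stop("probabilities must lie in [0, 1]")
  }
  structure(c(p, list(preset = preset)), class = "phenotype_params")
}

#' Cohort layout configuration
#'
#' Defaults mirror the study enrollment: 122 TD and 94 ADHD children in
#' three age groups (5-6, 7-8, 9-10 years), with 12 formal trials per task
#' (each of the 6 stimulus positions twice). The default simulator sampling
#' rate is 250 Hz; the recording-grade 1200 Hz is available but slower to
#' synthesize.
#'
#' @param n_td,n_adhd group sizes.
#' @param sampling_rate_hz simulator sampling rate (>= 60).
#' @param trials_per_task formal trials per task.
#' @param seed random seed for the whole cohort.
#' @param adhd_male_prob,td_male_prob sex ratios per group.
#' @param age_group_probs_td,age_group_probs_adhd sampling weights of the
#'   three age groups.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_td = 122, n_adhd = 94, sampling_rate_hz = 250,
                          trials_per_task = 12, seed = 1,
                          td_male_prob = 0.5, adhd_male_prob = 84 / 94,
                          age_group_probs_td = c(44, 45, 33) / 122,
                          age_group_probs_adhd = c(36, 37, 21) / 94) {
  stopifnot(n_td >= 1, n_adhd >= 1, sampling_rate_hz >= 60,
            trials_per_task %% 6 == 0)
  structure(list(n_td = n_td, n_adhd = n_adhd,
                 sampling_rate_hz = sampling_rate_hz,
                 trials_per_task = trials_per_task, seed = seed,
                 td_male_prob = td_male_prob,
                 adhd_male_prob = adhd_male_prob,
                 age_group_probs_td = age_group_probs_td,
                 age_group_probs_adhd = age_group_probs_adhd),
            class = "cohort_config")
}

min_jerk <- function(tau) 10 * tau^3 - 15 * tau^4 + 6 * tau^5

## duration (ms) of a minimum-jerk saccade of amplitude amp (deg) whose peak
## velocity is vpeak (deg/s); the profile's peak velocity is 1.875 amp / dur
saccade_duration_ms <- function(amp_deg, vpeak) {
  pmax(1.875 * amp_deg / pmax(vpeak, 50) * 1000, 10)
}

rand_ua_point <- function(aois) {
  W <- aois$screen_px[1]; H <- aois$screen_px[2]
  y_low <- runif(1) < 0.5
  y <- if (y_low) runif(1, 60, aois$band[["y0"]] - 40)
       else runif(1, aois$band[["y1"]] + 40, H - 60)
  c(runif(1, 80, W - 80), y)
}

rand_annulus_point <- function(aois) {
  ta <- aois$TA
  l_ta <- ta[["x1"]] - ta[["x0"]]
  cx <- (ta[["x0"]] + ta[["x1"]]) / 2
  cy <- (ta[["y0"]] + ta[["y1"]]) / 2
  W <- aois$screen_px[1]; H <- aois$screen_px[2]
  for (i in 1:25) {
    r <- runif(1, 1.05, 1.45) * l_ta
    th <- runif(1, 0, 2 * pi)
    x <- cx + r * cos(th); y <- cy + r * sin(th)
    if (x > 10 && x < W - 10 && y > 10 && y < H - 10 &&
        !point_in_rect(x, y, ta)) {
      return(c(x, y))
    }
  }
  c(cx, max(cy - 1.2 * l_ta, 20))
}

#' Synthesize the raw gaze stream of one trial
#'
#' Builds an intended fixation/saccade plan honoring the task timeline —
#' central fixation, phenotype-driven excursions (unrelated-area fixations,
#' intrusive saccades, wrong-period target fixations), latency-delayed
#' response saccade with optional direction errors and search fixations, and
#' completion or timeout — then samples it at the requested rate with
#' minimum-jerk saccade kinematics, additive gaze noise, a drifting noisy
#' pupil signal with occasional step artifacts, and blink-like validity
#' gaps.
#'
#' @param phenotype a [phenotype_params()].
#' @param spec a [trial_spec()].
#' @param screen a [screen_config()].
#' @param rate_hz sampling rate in Hz.
#' @return List with `samples` (dialect columns except ids, `timestamp_ms`
#'   relative to trial onset), `truth` (the planned fixations with intent
#'   labels) and `t_end` (trial duration in ms).
#' @export
generate_trial <- function(phenotype, spec, screen, rate_hz = 250) {
  aois <- build_aois(spec, screen)
  cx <- aois$center[1]; cy <- aois$center[2]
  jit <- function(p, s = phenotype$fix_jitter_px) p + rnorm(2, 0, s)
  ta_c <- c((aois$TA[["x0"]] + aois$TA[["x1"]]) / 2,
            (aois$TA[["y0"]] + aois$TA[["y1"]]) / 2)
  sa_c <- c((aois$SA[["x0"]] + aois$SA[["x1"]]) / 2,
            (aois$SA[["y0"]] + aois$SA[["y1"]]) / 2)
  resp_ref <- if (spec$task == "delayed") spec$cue_onset else spec$stimulus_onset
  latency <- max(80, rnorm(1, phenotype$latency_mean_ms,
                           phenotype$latency_sd_ms))
  complete <- runif(1) < phenotype$completion_prob

  ## planned excursions away from the initial central fixation
  exc <- list()
  if (spec$task != "delayed") {
    n_ua <- min(stats::rpois(1, phenotype$ua_fix_rate), 2L)
    if (n_ua > 0) {
      at <- sort(runif(n_ua, 250, 1050))
      for (k in seq_len(n_ua)) {
        exc[[length(exc) + 1L]] <- list(t = at[k], pos = rand_ua_point(aois),
                                        dwell = runif(1, 150, 250),
                                        label = "UA")
      }
    }
  } else {
    if (runif(1) < phenotype$intrusive_prob) {
      exc[[length(exc) + 1L]] <- list(t = runif(1, 300, 1100),
                                      pos = rand_ua_point(aois),
                                      dwell = runif(1, 150, 250),
                                      label = "intrusive")
    }
    if (runif(1) < phenotype$ta_wrong_prob) {
      exc[[length(exc) + 1L]] <- list(t = runif(1, 1600, 2100),
                                      pos = jit(ta_c, phenotype$fix_jitter_px / 2),
                                      dwell = runif(1, 180, 300),
                                      label = "TA_wrong")
    }
  }

  ## response chain after the permitting event
  chain <- list()
  if (spec$task == "antisaccade") {
    if (runif(1) < phenotype$direction_error_prob) {
      ## reflexive glance toward the stimulus that under/overshoots the
      ## stimulus square, landing in the wrong-side area of the band
      half <- aois$stim_size_px / 2
      dx <- runif(1, 1.2, 1.8) * half * sample(c(-1, 1), 1)
      err <- c(sa_c[1] + dx, cy + rnorm(1, 0, 20))
      err[1] <- min(max(err[1], 10), aois$screen_px[1] - 10)
      err[2] <- min(max(err[2], aois$band[["y0"]] + 10),
                    aois$band[["y1"]] - 10)
      chain[[length(chain) + 1L]] <- list(pos = err,
                                          dwell = runif(1, 150, 280),
                                          label = "direction_error")
    }
    if (runif(1) < phenotype$search_prob) {
      n_s <- max(2L, stats::rpois(1, phenotype$search_n_mean))
      for (k in seq_len(min(n_s, 4L))) {
        chain[[length(chain) + 1L]] <- list(pos = rand_annulus_point(aois),
                                            dwell = runif(1, 140, 240),
                                            label = "search")
      }
    }
  }
  if (complete) {
    chain[[length(chain) + 1L]] <- list(pos = jit(ta_c,
                                                  phenotype$fix_jitter_px / 2),
                                        dwell = spec$dwell_ms + runif(1, 100, 200),
                                        label = "TA")
  } else {
    n_w <- 2L + stats::rpois(1, 1)
    for (k in seq_len(n_w)) {
      chain[[length(chain) + 1L]] <- list(
        pos = if (runif(1) < 0.5) rand_annulus_point(aois) else rand_ua_point(aois),
        dwell = runif(1, 200, 400), label = "wander")
    }
  }

  ## walk the plan into concrete fixation intervals
  fx_x <- fx_y <- fx_t0 <- fx_t1 <- numeric(0)
  fx_lab <- character(0)
  center_pos <- jit(c(cx, cy), phenotype$fix_jitter_px / 2)
  add_fix <- function(pos, t0, t1, lab) {
    fx_x <<- c(fx_x, pos[1]); fx_y <<- c(fx_y, pos[2])
    fx_t0 <<- c(fx_t0, t0); fx_t1 <<- c(fx_t1, t1)
    fx_lab <<- c(fx_lab, lab)
  }
  vpeak <- function() max(120, rnorm(1, phenotype$peak_velocity_mean,
                                     phenotype$peak_velocity_sd))
  sac_dur <- function(a, b) {
    amp <- abs(px_to_deg(sqrt(sum((b - a)^2)), screen))
    saccade_duration_ms(amp, vpeak())
  }
  cur_t <- 0
  cur_pos <- center_pos
  cur_lab <- "CA"
  ## excursions interleave with returns to center
  for (e in exc) {
    d1 <- sac_dur(cur_pos, e$pos)
    if (e$t - d1 < cur_t + 100) next
    add_fix(cur_pos, cur_t, e$t - d1, cur_lab)
    add_fix(e$pos, e$t, e$t + e$dwell, e$label)
    d2 <- sac_dur(e$pos, center_pos)
    cur_t <- e$t + e$dwell + d2
    cur_pos <- center_pos
    cur_lab <- "CA"
  }
  ## hold center until the response saccade leaves
  arrive <- resp_ref + latency
  first <- chain[[1]]
  d1 <- sac_dur(cur_pos, first$pos)
  add_fix(cur_pos, cur_t, max(arrive - d1, cur_t + 60), cur_lab)
  t <- max(arrive, cur_t + 60 + d1)
  prev_pos <- NULL
  for (w in chain) {
    if (!is.null(prev_pos)) t <- t + sac_dur(prev_pos, w$pos)
    add_fix(w$pos, t, t + w$dwell, w$label)
    t <- t + w$dwell
    prev_pos <- w$pos
  }
  t_end <- if (spec$task == "delayed") {
    spec$trial_end
  } else if (complete) {
    min(t + runif(1, 30, 80), spec$trial_end)
  } else {
    spec$trial_end
  }
  ## clip the plan to the trial span and extend the last fixation to the end
  keep <- fx_t0 < t_end
  fx_x <- fx_x[keep]; fx_y <- fx_y[keep]
  fx_t0 <- fx_t0[keep]; fx_t1 <- pmin(fx_t1[keep], t_end)
  fx_lab <- fx_lab[keep]
  fx_t1[length(fx_t1)] <- t_end
  plan <- data.frame(x = fx_x, y = fx_y, t_start = fx_t0, t_end = fx_t1,
                     label = fx_lab, stringsAsFactors = FALSE)

  ## sample the plan
  step <- 1000 / rate_hz
  ts <- seq(0, t_end, by = step)
  n <- length(ts)
  bounds <- as.vector(rbind(plan$t_start, plan$t_end))
  seg <- findInterval(ts, bounds)
  gx <- gy <- numeric(n)
  in_fix <- seg %% 2 == 1
  fi <- (seg + 1) %/% 2
  fi_c <- pmin(pmax(fi, 1), nrow(plan))
  gx[in_fix] <- plan$x[fi_c[in_fix]]
  gy[in_fix] <- plan$y[fi_c[in_fix]]
  btw <- !in_fix & seg > 0 & seg < 2 * nrow(plan)
  if (any(btw)) {
    k <- seg[btw] / 2
    t0 <- plan$t_end[k]; t1 <- plan$t_start[k + 1]
    tau <- (ts[btw] - t0) / pmax(t1 - t0, 1e-6)
    s <- min_jerk(pmin(pmax(tau, 0), 1))
    gx[btw] <- plan$x[k] + s * (plan$x[k + 1] - plan$x[k])
    gy[btw] <- plan$y[k] + s * (plan$y[k + 1] - plan$y[k])
  }
  pre <- seg == 0
  gx[pre] <- plan$x[1]; gy[pre] <- plan$y[1]
  post <- seg >= 2 * nrow(plan)
  gx[post] <- plan$x[nrow(plan)]; gy[post] <- plan$y[nrow(plan)]
  gx <- gx + rnorm(n, 0, phenotype$gaze_noise_px)
  gy <- gy + rnorm(n, 0, phenotype$gaze_noise_px)
  W <- screen$resolution_px[1]; H <- screen$resolution_px[2]
  gx <- pmin(pmax(gx, 0), W - 1)
  gy <- pmin(pmax(gy, 0), H - 1)

  ## pupil: baseline + slow drift + noise + step artifacts, per eye
  base <- phenotype$pupil_baseline_mm + rnorm(1, 0, phenotype$pupil_sd_mm)
  drift_amp <- phenotype$pupil_sd_mm * sqrt(2)
  phase <- runif(1, 0, 2 * pi)
  p0 <- base + drift_amp * sin(2 * pi * ts / 3000 + phase)
  pl <- p0 + rnorm(n, 0, phenotype$pupil_noise_mm)
  pr <- p0 + rnorm(n, 0, phenotype$pupil_noise_mm)
  n_art <- stats::rpois(1, phenotype$artifact_rate)
  if (n_art > 0 && n > 5) {
    for (k in seq_len(n_art)) {
      at <- sample.int(n - 3, 1)
      len <- sample(1:3, 1)
      mag <- sample(c(-1, 1), 1) * runif(1, 1.5, 3)
      idx <- at:(at + len - 1)
      pl[idx] <- pl[idx] + mag
      pr[idx] <- pr[idx] + mag
    }
  }
  valid <- rep(1L, n)
  n_blink <- stats::rpois(1, phenotype$blink_rate)
  if (n_blink > 0 && n > 30) {
    for (k in seq_len(n_blink)) {
      at <- sample.int(n - 30, 1)
      len <- max(2L, round(runif(1, 80, 150) / step))
      idx <- at:min(at + len - 1, n)
      valid[idx] <- 0L
    }
  }
  gx[valid == 0] <- NA_real_
  gy[valid == 0] <- NA_real_
  pl[valid == 0] <- NA_real_
  pr[valid == 0] <- NA_real_
  samples <- data.frame(timestamp_ms = ts, gaze_x_px = gx, gaze_y_px = gy,
                        pupil_left_mm = pl, pupil_right_mm = pr,
                        valid_left = valid, valid_right = valid)
  list(samples = samples, truth = plan, t_end = t_end,
       latency = latency, complete = complete)
}

#' Lay out the participants and trial markers of a synthetic cohort
#'
#' Deterministically (given the config seed) assigns participant ids, group
#' labels, sex, age and age group, and the full trial sequence per
#' participant: the three tasks in order prosaccade, antisaccade, delayed
#' saccade, each with `trials_per_task` trials covering every
#' (side, eccentricity) position `trials_per_task / 6` times in shuffled
#' order. No gaze samples are synthesized, so the enrollment structure is
#' available instantly.
#'
#' @param config a [cohort_config()].
#' @return List with data frames `participants` (`participant_id`, `group`,
#'   `sex`, `age`, `age_group`) and `trials` (`participant_id`, `trial_id`,
#'   `task`, `eccentricity_deg`, `side`, `order`).
#' @export
cohort_design <- function(config = cohort_config()) {
  set.seed(config$seed)
  n <- config$n_td + config$n_adhd
  group <- c(rep("TD", config$n_td), rep("ADHD", config$n_adhd))
  pid <- sprintf("P%04d", seq_len(n))
  male_p <- ifelse(group == "ADHD", config$adhd_male_prob, config$td_male_prob)
  sex <- ifelse(runif(n) < male_p, "M", "F")
  age_group <- integer(n)
  age_group[group == "TD"] <- sample(1:3, config$n_td, TRUE,
                                     config$age_group_probs_td)
  age_group[group == "ADHD"] <- sample(1:3, config$n_adhd, TRUE,
                                       config$age_group_probs_adhd)
  age_lo <- c(5, 7, 9)[age_group]
  age <- age_lo + sample(0:1, n, TRUE) + sample(0:9, n, TRUE) / 10
  participants <- data.frame(participant_id = pid, group = group, sex = sex,
                             age = age, age_group = age_group,
                             stringsAsFactors = FALSE)
  reps <- config$trials_per_task / 6
  pos <- expand.grid(side = c("left", "right"),
                     eccentricity_deg = c(7, 15, 20),
                     stringsAsFactors = FALSE)
  trials <- do.call(rbind, lapply(seq_len(n), function(i) {
    per_task <- lapply(c("prosaccade", "antisaccade", "delayed"), function(tk) {
      idx <- rep(seq_len(nrow(pos)), reps)
      ord <- rep(seq_len(reps), each = nrow(pos))
      sh <- sample(length(idx))
      data.frame(participant_id = pid[i],
                 task = tk,
                 eccentricity_deg = pos$eccentricity_deg[idx[sh]],
                 side = pos$side[idx[sh]],
                 order = ord[sh],
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, per_task)
    out$trial_id <- seq_len(nrow(out))
    out[, c("participant_id", "trial_id", "task", "eccentricity_deg",
            "side", "order")]
  }))
  rownames(trials) <- NULL
  list(participants = participants, trials = trials)
}

#' Generate a full synthetic cohort of raw gaze recordings
#'
#' Draws the cohort layout with [cohort_design()] and synthesizes every
#' trial with [generate_trial()], concatenating all participants into one
#' gaze stream (dialect columns), one marker table, the participants table
#' and a ground-truth event log. Deterministic given the config seed.
#'
#' @param config a [cohort_config()].
#' @param td,adhd [phenotype_params()] for the two groups.
#' @param screen a [screen_config()].
#' @param inter_trial_ms clock gap inserted between successive trials.
#' @return List with `gaze`, `markers`, `participants`, `truth`.
#' @export
generate_cohort <- function(config = cohort_config(),
                            td = phenotype_params("TD-like"),
                            adhd = phenotype_params("ADHD-like"),
                            screen = screen_config(
                              sampling_rate_hz = config$sampling_rate_hz),
                            inter_trial_ms = 500) {
  design <- cohort_design(config)
  participants <- design$participants
  trials <- design$trials
  gaze_parts <- vector("list", nrow(trials))
  truth_parts <- vector("list", nrow(trials))
  onset <- numeric(nrow(trials))
  clock <- stats::setNames(rep(0, nrow(participants)),
                           participants$participant_id)
  for (i in seq_len(nrow(trials))) {
    tr <- trials[i, ]
    grp <- participants$group[match(tr$participant_id,
                                    participants$participant_id)]
    phen <- if (grp == "ADHD") adhd else td
    spec <- trial_spec(tr$task, tr$eccentricity_deg, tr$side, tr$order)
    g <- generate_trial(phen, spec, screen, config$sampling_rate_hz)
    t0 <- clock[[tr$participant_id]]
    onset[i] <- t0
    smp <- g$samples
    smp$timestamp_ms <- smp$timestamp_ms + t0
    gaze_parts[[i]] <- data.frame(participant_id = tr$participant_id,
                                  trial_id = tr$trial_id, smp,
                                  stringsAsFactors = FALSE)
    tru <- g$truth
    tru$participant_id <- tr$participant_id
    tru$trial_id <- tr$trial_id
    truth_parts[[i]] <- tru
    clock[[tr$participant_id]] <- t0 + g$t_end + inter_trial_ms
  }
  gaze <- do.call(rbind, gaze_parts)
  gaze <- gaze[, GAZE_COLUMNS]
  markers <- data.frame(trials[, c("participant_id", "trial_id", "task",
                                   "eccentricity_deg", "side", "order")],
                        onset_ms = onset, stringsAsFactors = FALSE)
  list(gaze = gaze, markers = markers, participants = participants,
       truth = do.call(rbind, truth_parts))
}

#' Write a synthetic cohort to disk in the gaze dialect
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_gaze_file(cohort$gaze, file.path(dir, "gaze.csv"))
  write_marker_file(cohort$markers, file.path(dir, "markers.csv"))
  utils::write.csv(cohort$participants,
                   file.path(dir, "participants.csv"), row.names = FALSE)
  utils::write.csv(cohort$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  invisible(dir)
}
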