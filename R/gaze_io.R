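#' @name gaze-dialect
#' @title The plain-text gaze dialect
#' @description
#' Raw recordings are exchanged as UTF-8 comma-separated files. The gaze file
#' has one row per sample with columns `participant_id, trial_id,
#' timestamp_ms, gaze_x_px, gaze_y_px, pupil_left_mm, pupil_right_mm,
#' valid_left, valid_right`; missing measurements are empty fields, never
#' zeros. The companion marker file has one row per trial: `participant_id,
#' trial_id, task, eccentricity_deg, side, order, onset_ms`, where `onset_ms`
#' is the trial's start (central cross onset) on the recording clock.
NULL

GAZE_COLUMNS <- c("participant_id", "trial_id", "timestamp_ms",
                  "gaze_x_px", "gaze_y_px", "pupil_left_mm", "pupil_right_mm",
                  "valid_left", "valid_right")

MARKER_COLUMNS <- c("participant_id", "trial_id", "task", "eccentricity_deg",
                    "side", "order", "onset_ms")

#' Read a raw gaze-sample file
#'
#' Parses the documented comma-separated gaze dialect (see
#' \link[=gaze-dialect]{gaze-dialect}). Empty fields become `NA`, and
#' timestamps are checked to be nondecreasing within each participant's
#' stream.
#'
#' @param path file path.
#' @param tolerance_ms allowed backward jitter in timestamps before a format
#'   error is raised.
#' @return A data frame of gaze samples.
#' @export
read_gaze_file <- function(path, tolerance_ms = 0) {
  if (!file.exists(path)) stop("gaze file not found: ", path)
  line1 <- readLines(path, n = 1L)
  if (!length(line1)) stop("format error: empty gaze file: ", path)
  header <- strsplit(line1, ",", fixed = TRUE)[[1]]
  if (!identical(header, GAZE_COLUMNS)) {
    bad <- setdiff(header, GAZE_COLUMNS)
    stop("format error (line 1): unexpected gaze columns: ",
         paste(c(bad, setdiff(GAZE_COLUMNS, header)), collapse = ", "))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(participant_id = "character",
                                       trial_id = "integer"))
  if (!nrow(df)) stop("format error: empty gaze file: ", path)
  for (pid in unique(df$participant_id)) {
    ts <- df$timestamp_ms[df$participant_id == pid]
    bad <- which(diff(ts) < -tolerance_ms)
    if (length(bad)) {
      stop(sprintf("format error (line %d): nonmonotone timestamps for %s",
                   bad[1] + 1L, pid))
    }
  }
  df$valid_left <- as.integer(df$valid_left)
  df$valid_right <- as.integer(df$valid_right)
  df
}

#' Write gaze samples in the canonical dialect
#'
#' @param samples data frame with the gaze-dialect columns.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gaze_file <- function(samples, path) {
  stopifnot(identical(names(samples), GAZE_COLUMNS))
  utils::write.csv(samples, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read / write the trial-marker file
#'
#' @param path file path.
#' @return A data frame of trial markers.
#' @export
read_marker_file <- function(path) {
  if (!file.exists(path)) stop("marker file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(participant_id = "character",
                                       trial_id = "integer"))
  if (!identical(names(df), MARKER_COLUMNS)) {
    stop("format error: unexpected marker columns")
  }
  if (!all(df$task %in% c("prosaccade", "antisaccade", "delayed"))) {
    stop("format error: unknown task in marker file")
  }
  df
}

#' @rdname read_marker_file
#' @param markers data frame of markers.
#' @export
write_marker_file <- function(markers, path) {
  stopifnot(identical(names(markers), MARKER_COLUMNS))
  utils::write.csv(markers, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Fraction of valid samples and the participant inclusion rule
#'
#' A sample is valid when at least one eye carries a validity flag. A
#' participant is included in analyses when strictly more than 80% of their
#' samples are valid.
#'
#' @param samples data frame with `valid_left` and `valid_right` columns.
#' @return `validity_fraction`: fraction in `[0, 1]`.
#' @export
validity_fraction <- function(samples) {
  if (!nrow(samples)) stop("empty sample stream")
  mean(samples$valid_left == 1 | samples$valid_right == 1)
}

#' @rdname validity_fraction
#' @param fraction a validity fraction.
#' @param threshold inclusion threshold (exclusive).
#' @return `include_participant`: logical.
#' @export
include_participant <- function(fraction, threshold = 0.8) {
  fraction > threshold
}

#' I-VT event-detection parameters
#'
#' Velocity-threshold classification parameters: samples whose angular gaze
#' velocity exceeds `velocity_threshold` (deg/s) are saccade samples, the
#' rest fixation samples; contiguous runs become events, fixations shorter
#' than `min_fixation_ms` are discarded, and gaps of missing data up to
#' `max_gap_ms` inside an event are bridged while longer gaps split events.
#' Velocity is computed by central differences on an angular position signal
#' smoothed with a centered moving average of `smooth_samples` samples.
#'
#' @param velocity_threshold saccade velocity threshold in deg/s.
#' @param min_fixation_ms minimum fixation duration in ms.
#' @param max_gap_ms maximum bridgeable gap in ms.
#' @param smooth_samples width (odd) of the position smoothing window.
#' @return A list of class `ivt_config`.
#' @export
ivt_config <- function(velocity_threshold = 30, min_fixation_ms = 60,
                       max_gap_ms = 75, smooth_samples = 3) {
  structure(list(velocity_threshold = velocity_threshold,
                 min_fixation_ms = min_fixation_ms,
                 max_gap_ms = max_gap_ms,
                 smooth_samples = as.integer(smooth_samples)),
            class = "ivt_config")
}

moving_average <- function(x, k) {
  if (k <= 1 || length(x) < k) return(x)
  f <- stats::filter(x, rep(1 / k, k), sides = 2)
  out <- as.numeric(f)
  na <- is.na(out)
  out[na] <- x[na]
  out
}

#' Detect fixations and saccades with the I-VT algorithm
#'
#' Classifies a single continuous stream of gaze samples (typically one
#' trial) into chronological, non-overlapping fixation and saccade events.
#' Gaze positions are converted to visual angles via the tangent model,
#' smoothed, and differentiated centrally; see [ivt_config()] for the
#' classification rules. Binocular position is assumed already merged into
#' `gaze_x_px`/`gaze_y_px`.
#'
#' @param samples data frame with `timestamp_ms`, `gaze_x_px`, `gaze_y_px`,
#'   `valid_left`, `valid_right`.
#' @param screen a [screen_config()].
#' @param ivt an [ivt_config()].
#' @return List with data frames `fixations` (`t_start`, `t_end`, `duration`,
#'   `x`, `y`) and `saccades` (`t_start`, `t_end`, `duration`, `amplitude`,
#'   `mean_velocity`, `peak_velocity`).
#' @export
detect_events <- function(samples, screen, ivt = ivt_config()) {
  empty_fix <- data.frame(t_start = numeric(0), t_end = numeric(0),
                          duration = numeric(0), x = numeric(0), y = numeric(0))
  empty_sac <- data.frame(t_start = numeric(0), t_end = numeric(0),
                          duration = numeric(0), amplitude = numeric(0),
                          mean_velocity = numeric(0), peak_velocity = numeric(0))
  ok <- (samples$valid_left == 1 | samples$valid_right == 1) &
    !is.na(samples$gaze_x_px) & !is.na(samples$gaze_y_px)
  ok[is.na(ok)] <- FALSE
  if (sum(ok) < 2) {
    warning("fewer than 2 valid gaze samples; no events detected")
    return(list(fixations = empty_fix, saccades = empty_sac))
  }
  t <- samples$timestamp_ms[ok]
  px <- samples$gaze_x_px[ok]
  py <- samples$gaze_y_px[ok]
  cx <- screen$resolution_px[1] / 2
  cy <- screen$resolution_px[2] / 2
  thx <- px_to_deg(px - cx, screen)
  thy <- px_to_deg(py - cy, screen)
  sx <- moving_average(thx, ivt$smooth_samples)
  sy <- moving_average(thy, ivt$smooth_samples)
  n <- length(t)
  ## central-difference angular velocity (one-sided at the ends)
  i0 <- c(1L, seq_len(n - 1L))
  i1 <- c(seq_len(n - 1L) + 1L, n)
  dt <- pmax(t[i1] - t[i0], 1e-9)
  vel <- sqrt((sx[i1] - sx[i0])^2 + (sy[i1] - sy[i0])^2) / dt * 1000
  is_sac <- vel > ivt$velocity_threshold
  ## split runs on class change or on unbridgeable time gaps
  gap_break <- c(FALSE, diff(t) > ivt$max_gap_ms)
  new_run <- c(TRUE, is_sac[-1] != is_sac[-n]) | gap_break
  run_id <- cumsum(new_run)
  fixations <- list()
  saccades <- list()
  for (rid in unique(run_id)) {
    idx <- which(run_id == rid)
    t0 <- t[idx[1]]
    t1 <- t[idx[length(idx)]]
    dur <- t1 - t0
    if (is_sac[idx[1]]) {
      if (dur <= 0) next
      amp <- sqrt((thx[idx[length(idx)]] - thx[idx[1]])^2 +
                    (thy[idx[length(idx)]] - thy[idx[1]])^2)
      saccades[[length(saccades) + 1L]] <-
        c(t0, t1, dur, amp, mean(vel[idx]), max(vel[idx]))
    } else {
      if (dur < ivt$min_fixation_ms) next
      fixations[[length(fixations) + 1L]] <-
        c(t0, t1, dur, mean(px[idx]), mean(py[idx]))
    }
  }
  fx <- if (length(fixations)) {
    m <- do.call(rbind, fixations)
    data.frame(t_start = m[, 1], t_end = m[, 2], duration = m[, 3],
               x = m[, 4], y = m[, 5])
  } else empty_fix
  sc <- if (length(saccades)) {
    m <- do.call(rbind, saccades)
    data.frame(t_start = m[, 1], t_end = m[, 2], duration = m[, 3],
               amplitude = m[, 4], mean_velocity = m[, 5],
               peak_velocity = m[, 6])
  } else empty_sac
  list(fixations = fx, saccades = sc)
}

#' Merge binocular gaze positions into a cyclopean signal
#'
#' The binocular gaze position is the average of the valid eyes; one-eyed
#' samples use the valid eye alone. For dialect files that already carry a
#' single merged position this is the identity.
#'
#' @param samples gaze-sample data frame.
#' @return The data frame with `gaze_x_px`/`gaze_y_px` set to `NA` where no
#'   eye is valid.
#' @export
merge_binocular <- function(samples) {
  none <- samples$valid_left != 1 & samples$valid_right != 1
  samples$gaze_x_px[none] <- NA_real_
  samples$gaze_y_px[none] <- NA_real_
  samples
}

#' Segment a gaze stream into trial records
#'
#' Cuts each participant's stream at the trial markers and attaches the
#' trial's specification, samples (timestamps re-based to the trial onset)
#' and, optionally, detected events. A trial spans its marker onset up to the
#' next marker of the same participant (or the end of the stream); an event
#' straddling a boundary belongs to the trial containing its start. Trials
#' without samples are flagged incomplete.
#'
#' @param gaze gaze-sample data frame (dialect columns).
#' @param markers trial-marker data frame, sorted by onset within
#'   participant.
#' @param screen a [screen_config()].
#' @param detect also run [detect_events()] per trial.
#' @param ivt an [ivt_config()] used when `detect = TRUE`.
#' @param timeout_ms timeout handed to [trial_spec()].
#' @return A list of `trial_record` objects.
#' @export
segment_trials <- function(gaze, markers, screen, detect = TRUE,
                           ivt = ivt_config(), timeout_ms = 5000) {
  records <- vector("list", nrow(markers))
  key_g <- paste(gaze$participant_id, gaze$trial_id, sep = "\r")
  groups <- split(seq_len(nrow(gaze)), key_g)
  for (p in split(seq_len(nrow(markers)), markers$participant_id)) {
    on <- markers$onset_ms[p]
    if (any(diff(on[order(on)]) <= 0) && length(on) > 1) {
      stop("overlapping trial markers")
    }
  }
  for (i in seq_len(nrow(markers))) {
    mk <- markers[i, ]
    spec <- trial_spec(mk$task, mk$eccentricity_deg, mk$side, mk$order,
                       timeout_ms = timeout_ms)
    idx <- groups[[paste(mk$participant_id, mk$trial_id, sep = "\r")]]
    smp <- if (is.null(idx)) gaze[0, ] else gaze[idx, , drop = FALSE]
    if (nrow(smp)) {
      smp$timestamp_ms <- smp$timestamp_ms - mk$onset_ms
      smp <- merge_binocular(smp)
    }
    ev <- if (detect && nrow(smp) >= 2) {
      detect_events(smp, screen, ivt)
    } else {
      list(fixations = data.frame(), saccades = data.frame())
    }
    records[[i]] <- structure(
      list(participant_id = mk$participant_id,
           trial_id = mk$trial_id,
           spec = spec,
           samples = smp,
           fixations = ev$fixations,
           saccades = ev$saccades,
           incomplete = nrow(smp) == 0),
      class = "trial_record")
  }
  records
}
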