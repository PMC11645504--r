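#' Screen and viewing geometry
#'
#' Describes the physical recording setup: monitor resolution and physical
#' size, viewing distance, and the eye tracker's sampling rate. The defaults
#' correspond to a 24-inch 16:9 monitor at 1920x1080 viewed from 65 cm,
#' recorded at 1200 Hz.
#'
#' Pixel coordinates are 0-based with the origin at the top-left corner,
#' x increasing rightward and y downward. The pixel pitch must be (near)
#' isotropic: the x and y pixels-per-cm may differ by at most 1%.
#'
#' @param resolution_px integer vector `c(width, height)` in pixels.
#' @param physical_size_cm numeric vector `c(width, height)` in cm.
#' @param viewing_distance_cm eye-to-screen distance in cm.
#' @param sampling_rate_hz nominal sampling rate of the tracker in Hz.
#' @return An object of class `screen_config`.
#' @examples
#' scr <- screen_config()
#' scr$px_per_cm
#' @export
screen_config <- function(resolution_px = c(1920L, 1080L),
                          physical_size_cm = c(53.14, 29.89),
                          viewing_distance_cm = 65,
                          sampling_rate_hz = 1200) {
  stopifnot(length(resolution_px) == 2, length(physical_size_cm) == 2,
            length(viewing_distance_cm) == 1, length(sampling_rate_hz) == 1)
  if (any(resolution_px <= 0) || any(physical_size_cm <= 0) ||
      viewing_distance_cm <= 0 || sampling_rate_hz <= 0) {
    stop("all screen geometry values must be positive")
  }
  ppc <- as.numeric(resolution_px) / as.numeric(physical_size_cm)
  if (abs(ppc[1] - ppc[2]) / mean(ppc) > 0.01) {
    stop("anisotropic pixel pitch: x/y pixels-per-cm differ by more than 1%")
  }
  structure(
    list(resolution_px = as.numeric(resolution_px),
         physical_size_cm = as.numeric(physical_size_cm),
         viewing_distance_cm = as.numeric(viewing_distance_cm),
         sampling_rate_hz = as.numeric(sampling_rate_hz),
         px_per_cm = mean(ppc)),
    class = "screen_config")
}

#' @export
print.screen_config <- function(x, ...) {
  cat(sprintf("<screen_config> %dx%d px, %.2fx%.2f cm, %.0f cm distance, %g Hz\n",
              x$resolution_px[1], x$resolution_px[2],
              x$physical_size_cm[1], x$physical_size_cm[2],
              x$viewing_distance_cm, x$sampling_rate_hz))
  invisible(x)
}

#' Trial specification for one saccade-task trial
#'
#' Encodes the task type, stimulus eccentricity and side, the trial order
#' (each of the six stimulus positions appears twice per task), and the
#' timeline anchors in ms from trial start: the central cross appears at 0,
#' the stimulus at 1500 ms, and in the delayed task the auditory go-cue
#' sounds at 2500 ms with the trial ending 3000 ms later. Prosaccade and
#' antisaccade trials end when the participant has dwelt in the target region
#' for 300 ms (or at `timeout_ms`).
#'
#' @param task `"prosaccade"`, `"antisaccade"` or `"delayed"`.
#' @param eccentricity_deg stimulus eccentricity: 7, 15 or 20 degrees.
#' @param side `"left"` or `"right"`.
#' @param order trial order for this position, 1 or 2.
#' @param timeout_ms maximum trial duration for prosaccade/antisaccade trials.
#' @return An object of class `trial_spec`.
#' @export
trial_spec <- function(task = c("prosaccade", "antisaccade", "delayed"),
                       eccentricity_deg, side = c("left", "right"),
                       order = 1L, timeout_ms = 5000) {
  task <- match.arg(task)
  side <- match.arg(side)
  if (!eccentricity_deg %in% c(7, 15, 20)) {
    stop("eccentricity_deg must be one of 7, 15, 20")
  }
  if (!order %in% c(1L, 2L)) stop("order must be 1 or 2")
  delayed <- task == "delayed"
  structure(
    list(task = task,
         eccentricity_deg = as.numeric(eccentricity_deg),
         side = side,
         order = as.integer(order),
         cross_onset = 0,
         stimulus_onset = 1500,
         cue_onset = if (delayed) 2500 else NA_real_,
         trial_end = if (delayed) 2500 + 3000 else as.numeric(timeout_ms),
         dwell_ms = 300),
    class = "trial_spec")
}

task_letter <- function(task) {
  c(prosaccade = "P", antisaccade = "A", delayed = "D")[[task]]
}

#' Convert stimulus eccentricity to a horizontal pixel offset
#'
#' Uses the flat-screen tangent model: a target at visual angle `theta` sits
#' `d * tan(theta)` cm from the screen center along the horizontal axis, where
#' `d` is the viewing distance; the offset is converted to pixels with the
#' screen's pixels-per-cm.
#'
#' @param eccentricity_deg visual angle in degrees, in `[0, 90)`.
#' @param screen a [screen_config()].
#' @return Horizontal offset from screen center in pixels (unsigned).
#' @examples
#' eccentricity_to_px(7, screen_config())  # ~288 px
#' @export
eccentricity_to_px <- function(eccentricity_deg, screen) {
  stopifnot(inherits(screen, "screen_config"))
  if (any(eccentricity_deg < 0) || any(eccentricity_deg >= 90)) {
    stop("invalid geometry: eccentricity must lie in [0, 90) degrees")
  }
  screen$viewing_distance_cm * tan(eccentricity_deg * pi / 180) * screen$px_per_cm
}

#' Convert an on-screen pixel displacement to visual degrees
#'
#' Inverse of the tangent model used by [eccentricity_to_px()], applied to a
#' displacement measured from the screen center.
#'
#' @param px displacement in pixels.
#' @param screen a [screen_config()].
#' @return Visual angle in degrees.
#' @export
px_to_deg <- function(px, screen) {
  atan((px / screen$px_per_cm) / screen$viewing_distance_cm) * 180 / pi
}

## rectangles are half-open [x0, x1) x [y0, y1), stored c(x0, x1, y0, y1)
rect_center <- function(cx, cy, w, h) {
  c(x0 = cx - w / 2, x1 = cx + w / 2, y0 = cy - h / 2, y1 = cy + h / 2)
}

point_in_rect <- function(x, y, r) {
  x >= r[["x0"]] & x < r[["x1"]] & y >= r[["y0"]] & y < r[["y1"]]
}

#' Build the area-of-interest partition for one trial
#'
#' Divides the screen into the task's areas of interest: the center area (CA,
#' a 5x5 cm square around the fixation cross), the stimulus area (SA, the 5x5
#' cm stimulus square), the target area (TA; identical to SA for prosaccade
#' and delayed trials, its horizontal mirror about the screen center for
#' antisaccade trials), and the remaining screen. A horizontal band of height
#' `band_height_cm` centered on the stimulus axis holds the task-relevant
#' regions; everything outside the band is the unrelated area (UA). Within the
#' band, antisaccade trials further split the non-CA/TA/SA space at the
#' vertical midline into the proper-side area (PSA, target side) and the
#' wrong-side area (WSA, stimulus side); for prosaccade and delayed trials the
#' leftover band space belongs to UA. Every on-screen pixel receives exactly
#' one label.
#'
#' @param spec a [trial_spec()].
#' @param screen a [screen_config()].
#' @param stim_size_cm edge length of the stimulus/target square in cm.
#' @param band_height_cm height of the stimulus band in cm.
#' @return An object of class `aoi_set`: rectangles plus task metadata.
#' @export
build_aois <- function(spec, screen, stim_size_cm = 5, band_height_cm = 5) {
  stopifnot(inherits(spec, "trial_spec"), inherits(screen, "screen_config"))
  W <- screen$resolution_px[1]
  H <- screen$resolution_px[2]
  cx <- W / 2
  cy <- H / 2
  sz <- stim_size_cm * screen$px_per_cm
  bh <- band_height_cm * screen$px_per_cm
  off <- eccentricity_to_px(spec$eccentricity_deg, screen)
  sgn <- if (spec$side == "right") 1 else -1
  sa_cx <- cx + sgn * off
  ta_cx <- if (spec$task == "antisaccade") cx - sgn * off else sa_cx
  sa <- rect_center(sa_cx, cy, sz, sz)
  ta <- rect_center(ta_cx, cy, sz, sz)
  ca <- rect_center(cx, cy, sz, sz)
  for (r in list(sa, ta)) {
    if (r[["x0"]] < 0 || r[["x1"]] > W || r[["y0"]] < 0 || r[["y1"]] > H) {
      stop("invalid geometry: stimulus square extends off-screen")
    }
  }
  band <- c(x0 = 0, x1 = W, y0 = cy - bh / 2, y1 = cy + bh / 2)
  structure(
    list(task = spec$task, side = spec$side, screen_px = c(W, H),
         center = c(cx, cy), stim_size_px = sz,
         CA = ca, SA = sa, TA = ta, band = band,
         target_sign = sign(ta_cx - cx)),
    class = "aoi_set")
}

#' Label on-screen points with their area of interest
#'
#' Vectorized hit test against an [build_aois()] partition. Labels are
#' `"CA"`, `"TA"`, `"SA"` (antisaccade only: for prosaccade and delayed
#' trials the stimulus square IS the target and is labeled `"TA"`), `"PSA"`,
#' `"WSA"` (antisaccade only) and `"UA"`.
#'
#' @param x,y pixel coordinates (0-based, origin top-left).
#' @param aois an `aoi_set`.
#' @return Character vector of area labels.
#' @export
classify_points <- function(x, y, aois) {
  stopifnot(inherits(aois, "aoi_set"), length(x) == length(y))
  lab <- rep(NA_character_, length(x))
  in_band <- point_in_rect(x, y, aois$band)
  lab[!in_band] <- "UA"
  idx <- which(in_band)
  if (length(idx)) {
    xi <- x[idx]; yi <- y[idx]
    li <- rep(NA_character_, length(idx))
    li[point_in_rect(xi, yi, aois$CA)] <- "CA"
    li[is.na(li) & point_in_rect(xi, yi, aois$TA)] <- "TA"
    if (aois$task == "antisaccade") {
      li[is.na(li) & point_in_rect(xi, yi, aois$SA)] <- "SA"
      ## remaining band pixels split at the vertical midline: the half-open
      ## convention puts x == center on the right-hand side
      cx <- aois$center[1]
      on_target_side <- (ifelse(xi >= cx, 1, -1)) == aois$target_sign
      li[is.na(li)] <- ifelse(on_target_side[is.na(li)], "PSA", "WSA")
    } else {
      li[is.na(li)] <- "UA"
    }
    lab[idx] <- li
  }
  lab
}

#' Classify a fixation by area (and, for delayed trials, by period)
#'
#' Assigns the fixation's centroid an AOI label and, for delayed-saccade
#' trials, a period label from the fixation's start time: the enforced
#' central-fixation window `[0, 1500)` ms ("intrusive window": any fixation
#' leaving CA here is an intrusive saccade), the wrong period `[1500, 2500)`
#' (stimulus visible, cue not yet sounded; a TA hit counts toward
#' `N_TA-W_Fix`), and the proper period from the cue at 2500 ms onward (a TA
#' hit counts toward `N_TA-P_Fix`).
#'
#' @param fix a list or one-row data frame with `x`, `y` (centroid px) and
#'   `t_start` (ms from trial start).
#' @param aois an `aoi_set` for the trial.
#' @param spec the [trial_spec()].
#' @param clamp_offscreen clamp off-screen centroids onto the screen edge
#'   (default) instead of erroring.
#' @return A list with `area` and (delayed trials) `period`, one of
#'   `"intrusive-window"`, `"wrong-period"`, `"proper-period"`.
#' @export
classify_fixation <- function(fix, aois, spec, clamp_offscreen = TRUE) {
  x <- fix$x; y <- fix$y; t0 <- fix$t_start
  if (any(t0 < 0)) stop("fixation start time must be nonnegative")
  W <- aois$screen_px[1]; H <- aois$screen_px[2]
  off <- x < 0 | x >= W | y < 0 | y >= H
  if (any(off)) {
    if (!clamp_offscreen) stop("fixation centroid off-screen")
    x <- pmin(pmax(x, 0), W - 1e-9)
    y <- pmin(pmax(y, 0), H - 1e-9)
  }
  area <- classify_points(x, y, aois)
  if (spec$task != "delayed") {
    return(list(area = area, period = rep(NA_character_, length(area))))
  }
  period <- ifelse(t0 < spec$stimulus_onset, "intrusive-window",
                   ifelse(t0 < spec$cue_onset, "wrong-period", "proper-period"))
  list(area = area, period = period)
}

#' Grid partition of the screen for gaze-entropy metrics
#'
#' Tiles the screen with a regular grid of disjoint rectangles that serve as
#' the discrete state space of the gaze process: 6 areas (3x2) for the
#' prosaccade and delayed-saccade tasks and 8 areas (4x2) for the antisaccade
#' task by default. The maximum attainable entropy is `log2(n_areas)`.
#'
#' @param task task name, used to pick the default grid.
#' @param screen a [screen_config()].
#' @param dims optional `c(ncol, nrow)` overriding the default grid.
#' @return An object of class `entropy_partition`.
#' @export
entropy_partition <- function(task, screen, dims = NULL) {
  stopifnot(inherits(screen, "screen_config"))
  if (is.null(dims)) {
    dims <- if (task == "antisaccade") c(4L, 2L) else c(3L, 2L)
  }
  n <- prod(dims)
  structure(
    list(task = task, dims = as.integer(dims), n_areas = n,
         screen_px = screen$resolution_px, h_max = log2(n)),
    class = "entropy_partition")
}

#' Map points to entropy-grid cell indices
#'
#' @param x,y pixel coordinates.
#' @param partition an [entropy_partition()].
#' @return Integer cell index in `1..n_areas` (row-major from top-left).
#' @export
partition_index <- function(x, y, partition) {
  W <- partition$screen_px[1]; H <- partition$screen_px[2]
  nx <- partition$dims[1]; ny <- partition$dims[2]
  ix <- pmin(pmax(floor(x / (W / nx)), 0), nx - 1)
  iy <- pmin(pmax(floor(y / (H / ny)), 0), ny - 1)
  as.integer(iy * nx + ix + 1)
}

#' Paradigm configuration with optional YAML overrides
#'
#' Returns the full set of tunable constants of the pipeline — screen
#' geometry, AOI sizes, entropy grid dimensions, trial timeline anchors, and
#' I-VT event-detection parameters — optionally overridden by a plain-text
#' YAML file with the same nested names. Defaults are the recording setup and
#' paradigm constants of the assessment.
#'
#' @param file optional path to a YAML file; keys present in the file replace
#'   the corresponding defaults.
#' @return Nested list of configuration values.
#' @export
paradigm_config <- function(file = NULL) {
  cfg <- list(
    screen = list(resolution_px = c(1920L, 1080L),
                  physical_size_cm = c(53.14, 29.89),
                  viewing_distance_cm = 65,
                  sampling_rate_hz = 1200),
    aoi = list(stim_size_cm = 5, band_height_cm = 5),
    entropy = list(dims_pro = c(3L, 2L), dims_anti = c(4L, 2L)),
    timeline = list(stimulus_onset = 1500, cue_onset = 2500,
                    delayed_post_cue = 3000, dwell_ms = 300,
                    timeout_ms = 5000),
    ivt = list(velocity_threshold = 30, min_fixation_ms = 60,
               max_gap_ms = 75, smooth_samples = 3),
    pupil = list(range_mm = c(1.5, 9.0), mad_scalar = 1.5,
                 resample_hz = 500, window_samples = 20,
                 half_life_ms = 10, max_gap_ms = 50)
  )
  if (!is.null(file)) {
    user <- yaml::read_yaml(file)
    cfg <- utils::modifyList(cfg, user)
  }
  cfg
}
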