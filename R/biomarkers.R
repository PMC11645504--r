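#' The catalog of 28 per-trial digital biomarkers
#'
#' Enumerates every biomarker definition with its category and task
#' applicability: 8 general, 4 pupil-based, 11 area-based, 3 search-based and
#' 2 entropy-based metrics. Task applicability is encoded as a string over
#' `P` (prosaccade), `A` (antisaccade) and `D` (delayed saccade).
#'
#' @return Data frame with columns `metric`, `category`, `tasks`.
#' @examples
#' table(biomarker_catalog()$category)
#' @export
biomarker_catalog <- function() {
  m <- rbind(
    c("N_Fix",           "general", "PAD"),
    c("N_Sac",           "general", "PAD"),
    c("T_Total",         "general", "PAD"),
    c("T_Fix_Avg",       "general", "PAD"),
    c("T_Sac_Avg",       "general", "PAD"),
    c("V_Sac_Avg",       "general", "PAD"),
    c("V_Sac_Peak",      "general", "PAD"),
    c("A_Sac_Avg",       "general", "PAD"),
    c("D_Pupil_Avg",     "pupil",   "PAD"),
    c("D_Pupil_Max",     "pupil",   "PAD"),
    c("D_Pupil_Min",     "pupil",   "PAD"),
    c("D_Pupil_Sd",      "pupil",   "PAD"),
    c("B_TA_Fix",        "area",    "PAD"),
    c("L_TA_Fix",        "area",    "PAD"),
    c("N_UA_Fix",        "area",    "PA"),
    c("N_TA_Fix",        "area",    "D"),
    c("N_TA_P_Fix",      "area",    "D"),
    c("N_TA_W_Fix",      "area",    "D"),
    c("N_SA_Fix",        "area",    "A"),
    c("B_PSA_Fix",       "area",    "A"),
    c("B_WSA_Fix",       "area",    "A"),
    c("B_PSA_Fix_1st",   "area",    "A"),
    c("B_Intrusive_Sac", "area",    "D"),
    c("B_Search",        "search",  "A"),
    c("N_Search",        "search",  "A"),
    c("T_Search",        "search",  "A"),
    c("SGE_norm",        "entropy", "PAD"),
    c("GTE_norm",        "entropy", "PAD"))
  data.frame(metric = m[, 1], category = m[, 2], tasks = m[, 3],
             stringsAsFactors = FALSE)
}

metric_applicable <- function(metric, task, catalog = biomarker_catalog()) {
  grepl(task_letter(task), catalog$tasks[match(metric, catalog$metric)],
        fixed = TRUE)
}

#' General oculomotor metrics of a trial
#'
#' Fixation/saccade counts, trial duration, mean event durations, mean and
#' peak saccade velocity, and mean saccade amplitude. With no saccades (or no
#' fixations) the corresponding counts are zero and the means are `NA`.
#'
#' @param fixations,saccades event data frames from [detect_events()].
#' @param t_total total trial duration in ms (recorded span).
#' @return Named list of the 8 general metrics.
#' @export
general_metrics <- function(fixations, saccades, t_total) {
  nf <- nrow(fixations)
  ns <- nrow(saccades)
  list(
    N_Fix = nf,
    N_Sac = ns,
    T_Total = t_total,
    T_Fix_Avg = if (nf) mean(fixations$duration) else NA_real_,
    T_Sac_Avg = if (ns) mean(saccades$duration) else NA_real_,
    V_Sac_Avg = if (ns) mean(saccades$mean_velocity) else NA_real_,
    V_Sac_Peak = if (ns) max(saccades$peak_velocity) else NA_real_,
    A_Sac_Avg = if (ns) mean(saccades$amplitude) else NA_real_)
}

#' Area-based metrics of a trial
#'
#' Computes the Table-style area metrics applicable to the trial's task from
#' AOI-classified fixations. `B_TA_Fix` records whether any fixation landed
#' in the target area (for delayed trials, in the proper period only), and
#' `L_TA_Fix` is the latency of that first fixation relative to the
#' response-permitting event: the stimulus onset for prosaccade/antisaccade
#' trials and the auditory cue for delayed trials. `B_PSA_Fix_1st` is true
#' when the first post-stimulus fixation outside the center area lies in the
#' proper-side area; `B_Intrusive_Sac` when any fixation leaves the center
#' area during the enforced central-fixation window of a delayed trial.
#'
#' @param fixations fixation data frame (`t_start`, `t_end`, `duration`,
#'   `x`, `y`).
#' @param aois the trial's `aoi_set`.
#' @param spec the [trial_spec()].
#' @return Named list of the applicable area-based metrics.
#' @export
area_metrics <- function(fixations, aois, spec) {
  cl <- if (nrow(fixations)) {
    classify_fixation(fixations, aois, spec)
  } else {
    list(area = character(0), period = character(0))
  }
  area <- cl$area
  period <- cl$period
  out <- list()
  if (spec$task == "delayed") {
    ta_p <- area == "TA" & period == "proper-period"
    ta_w <- area == "TA" & period == "wrong-period"
    out$B_TA_Fix <- as.numeric(any(ta_p))
    out$L_TA_Fix <- if (any(ta_p)) {
      min(fixations$t_start[ta_p]) - spec$cue_onset
    } else NA_real_
    out$N_TA_Fix <- sum(area == "TA")
    out$N_TA_P_Fix <- sum(ta_p)
    out$N_TA_W_Fix <- sum(ta_w)
    out$B_Intrusive_Sac <-
      as.numeric(any(area != "CA" & period == "intrusive-window"))
  } else {
    post <- fixations$t_start >= spec$stimulus_onset
    ta <- area == "TA" & post
    out$B_TA_Fix <- as.numeric(any(ta))
    out$L_TA_Fix <- if (any(ta)) {
      min(fixations$t_start[ta]) - spec$stimulus_onset
    } else NA_real_
    out$N_UA_Fix <- sum(area == "UA")
    if (spec$task == "antisaccade") {
      out$N_SA_Fix <- sum(area == "SA")
      out$B_PSA_Fix <- as.numeric(any(area == "PSA"))
      out$B_WSA_Fix <- as.numeric(any(area == "WSA"))
      first_out <- which(post & area != "CA")
      out$B_PSA_Fix_1st <- as.numeric(length(first_out) > 0 &&
                                        area[first_out[1]] == "PSA")
    }
  }
  out
}

#' Detect search behavior around the antisaccade target
#'
#' Participants who struggle to localize the mirror-symmetric landing point
#' produce runs of fixations near but outside the target area. A fixation is
#' a search candidate when its centroid lies outside the TA square and within
#' a Euclidean distance of `1.5 * L_TA` of the TA center, where `L_TA` is the
#' TA edge length. Maximal runs of at least 2 chronologically consecutive
#' candidates form search events.
#'
#' @param fixations fixation data frame.
#' @param aois the trial's `aoi_set`.
#' @return List with `B_Search` (0/1), `N_Search`, `T_Search` (ms, total
#'   duration of member fixations) and the `events` (list of index vectors).
#' @export
detect_search <- function(fixations, aois) {
  if (!nrow(fixations)) {
    return(list(B_Search = 0, N_Search = 0L, T_Search = 0, events = list()))
  }
  ta <- aois$TA
  l_ta <- ta[["x1"]] - ta[["x0"]]
  ta_cx <- (ta[["x0"]] + ta[["x1"]]) / 2
  ta_cy <- (ta[["y0"]] + ta[["y1"]]) / 2
  inside_ta <- point_in_rect(fixations$x, fixations$y, ta)
  d <- sqrt((fixations$x - ta_cx)^2 + (fixations$y - ta_cy)^2)
  marked <- !inside_ta & d <= 1.5 * l_ta
  r <- rle(marked)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values & r$lengths >= 2)
  events <- lapply(runs, function(k) seq(starts[k], ends[k]))
  t_search <- sum(vapply(events, function(ix) sum(fixations$duration[ix]), 0))
  list(B_Search = as.numeric(length(events) > 0),
       N_Search = length(events),
       T_Search = t_search,
       events = events)
}

#' Stationary and transition gaze entropy
#'
#' The screen is tiled by an [entropy_partition()] whose cells form the state
#' space of the gaze process. With `p_i` the proportion of fixations in cell
#' `i`, the stationary gaze entropy is `SGE = -sum_i p_i log2 p_i`; with
#' `p(j|i)` the first-order Markov transition probabilities estimated from
#' the chronological fixation sequence, the gaze transition entropy is
#' `GTE = -sum_i p_i sum_j p(j|i) log2 p(j|i)`. Both are normalized by the
#' maximum entropy `log2 n` into `[0, 1]`, and `0 * log 0` is taken as 0.
#'
#' @param fixations fixation data frame (chronological).
#' @param partition an [entropy_partition()].
#' @param self_transitions count consecutive fixations in the same cell as
#'   transitions (default) or drop them.
#' @return List with `SGE_norm`, `GTE_norm` (plus unnormalized `SGE`, `GTE`).
#' @export
gaze_entropy <- function(fixations, partition, self_transitions = TRUE) {
  if (!nrow(fixations)) {
    return(list(SGE = NA_real_, GTE = NA_real_,
                SGE_norm = NA_real_, GTE_norm = NA_real_))
  }
  a <- partition_index(fixations$x, fixations$y, partition)
  n <- partition$n_areas
  counts <- tabulate(a, nbins = n)
  p <- counts / sum(counts)
  plogp <- ifelse(p > 0, p * log2(p), 0)
  sge <- -sum(plogp)
  gte <- 0
  if (length(a) >= 2) {
    from <- a[-length(a)]
    to <- a[-1]
    if (!self_transitions) {
      keep <- from != to
      from <- from[keep]
      to <- to[keep]
    }
    if (length(from)) {
      tm <- matrix(0, n, n)
      for (k in seq_along(from)) tm[from[k], to[k]] <- tm[from[k], to[k]] + 1
      rs <- rowSums(tm)
      h_row <- numeric(n)
      for (i in which(rs > 0)) {
        pj <- tm[i, ] / rs[i]
        h_row[i] <- -sum(ifelse(pj > 0, pj * log2(pj), 0))
      }
      gte <- sum(p * h_row)
    }
  }
  list(SGE = sge, GTE = gte,
       SGE_norm = sge / partition$h_max, GTE_norm = gte / partition$h_max)
}

#' Assemble all biomarkers of one trial
#'
#' Computes the applicable subset of the 28-biomarker catalog for a trial
#' record: general metrics from detected events, pupil metrics from the
#' preprocessing pipeline, area-based metrics from the AOI partition,
#' search-based metrics (antisaccade only) and normalized gaze entropies.
#' Metrics not applicable to the trial's task are `NA`.
#'
#' @param trial a `trial_record` from [segment_trials()].
#' @param screen a [screen_config()].
#' @param config a [paradigm_config()] list.
#' @return Named list covering all 28 catalog metrics (inapplicable = `NA`).
#' @export
compute_trial_biomarkers <- function(trial, screen,
                                     config = paradigm_config()) {
  spec <- trial$spec
  aois <- build_aois(spec, screen,
                     stim_size_cm = config$aoi$stim_size_cm,
                     band_height_cm = config$aoi$band_height_cm)
  dims <- if (spec$task == "antisaccade") config$entropy$dims_anti
          else config$entropy$dims_pro
  part <- entropy_partition(spec$task, screen, dims)
  fx <- trial$fixations
  sc <- trial$saccades
  t_total <- if (nrow(trial$samples)) {
    diff(range(trial$samples$timestamp_ms))
  } else NA_real_
  out <- stats::setNames(as.list(rep(NA_real_, 28)),
                         biomarker_catalog()$metric)
  gm <- general_metrics(fx, sc, t_total)
  out[names(gm)] <- gm
  pp <- preprocess_pupil(trial$samples,
                         range_mm = config$pupil$range_mm,
                         mad_scalar = config$pupil$mad_scalar,
                         rate_hz = config$pupil$resample_hz,
                         window = config$pupil$window_samples,
                         half_life_ms = config$pupil$half_life_ms,
                         max_gap_ms = config$pupil$max_gap_ms)
  out[names(pp$metrics)] <- pp$metrics
  am <- area_metrics(fx, aois, spec)
  out[names(am)] <- am
  if (spec$task == "antisaccade") {
    sr <- detect_search(fx, aois)
    out[c("B_Search", "N_Search", "T_Search")] <-
      sr[c("B_Search", "N_Search", "T_Search")]
  }
  ge <- gaze_entropy(fx, part)
  out[c("SGE_norm", "GTE_norm")] <- ge[c("SGE_norm", "GTE_norm")]
  out
}

#' Extract the per-trial biomarker table from raw streams
#'
#' End-to-end extraction: segments the gaze stream at the trial markers,
#' detects events, runs the pupil pipeline, and computes all applicable
#' biomarkers per trial. One output row per marker, with the four trial
#' attributes followed by the 28 metric columns.
#'
#' @param gaze gaze-sample data frame (dialect columns).
#' @param markers trial-marker data frame.
#' @param screen a [screen_config()].
#' @param config a [paradigm_config()] list.
#' @return Data frame: `participant_id`, `trial_id`, `task`,
#'   `eccentricity_deg`, `side`, `order`, then the 28 metrics.
#' @export
extract_biomarkers <- function(gaze, markers, screen = screen_config(),
                               config = paradigm_config()) {
  ivt <- do.call(ivt_config, config$ivt)
  records <- segment_trials(gaze, markers, screen, detect = TRUE, ivt = ivt,
                            timeout_ms = config$timeline$timeout_ms)
  rows <- lapply(records, function(tr) {
    bm <- compute_trial_biomarkers(tr, screen, config)
    c(list(participant_id = tr$participant_id, trial_id = tr$trial_id,
           task = tr$spec$task, eccentricity_deg = tr$spec$eccentricity_deg,
           side = tr$spec$side, order = tr$spec$order), bm)
  })
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
}
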