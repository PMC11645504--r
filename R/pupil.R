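#' Remove pupil samples outside the physiologically feasible range
#'
#' Drops samples flagged invalid by the tracker and samples whose pupil
#' diameter falls outside the feasible range of 1.5 to 9.0 mm (inclusive
#' bounds).
#'
#' @param trace data frame with columns `t` (ms) and `p` (mm), optionally
#'   `valid` (0/1).
#' @param range_mm numeric length-2, the feasible diameter range.
#' @return The filtered trace.
#' @export
range_filter <- function(trace, range_mm = c(1.5, 9.0)) {
  keep <- !is.na(trace$p) & trace$p >= range_mm[1] & trace$p <= range_mm[2]
  if (!is.null(trace$valid)) keep <- keep & trace$valid == 1
  out <- trace[keep, c("t", "p"), drop = FALSE]
  if (!nrow(out)) warning("range_filter removed every sample")
  rownames(out) <- NULL
  out
}

#' Normalized pupil dilation speed
#'
#' Because sampling intervals are not uniform, diameter changes between
#' adjacent samples are compared as per-millisecond speeds. Each interior
#' sample gets the larger of its backward and forward absolute speeds,
#'
#' \deqn{s_i = \max\left(\left|\frac{p_i - p_{i-1}}{t_i - t_{i-1}}\right|,
#'   \left|\frac{p_{i+1} - p_i}{t_{i+1} - t_i}\right|\right),}
#'
#' and the two endpoints use their single available one-sided speed.
#'
#' @param t strictly increasing timestamps in ms.
#' @param p pupil diameters in mm.
#' @return Vector of speeds in mm/ms, same length as `p`.
#' @export
dilation_speed <- function(t, p) {
  n <- length(p)
  stopifnot(length(t) == n)
  if (n < 2) return(rep(0, n))
  if (any(diff(t) <= 0)) stop("timestamps must be strictly increasing")
  d <- abs(diff(p) / diff(t))
  pmax(c(d[1], d), c(d, d[n - 1]))
}

#' Robust outlier threshold for dilation speeds
#'
#' The median absolute deviation of the speed sequence sets the threshold
#' `T = median(s) + n * MAD` with `MAD = median(|s - median(s)|)` and scalar
#' `n = 1.5`; speeds strictly above `T` mark blink or system-error artifacts.
#' When `MAD` is zero the threshold equals the median and only samples
#' strictly above it are flagged.
#'
#' @param s dilation-speed sequence (mm/ms).
#' @param n outlier scalar.
#' @return List with `median`, `mad`, `threshold`.
#' @export
speed_outlier_threshold <- function(s, n = 1.5) {
  med <- stats::median(s)
  mad <- stats::median(abs(s - med))
  list(median = med, mad = mad, threshold = med + n * mad)
}

#' Remove dilation-speed outliers from a pupil trace
#'
#' Applies [speed_outlier_threshold()] to the trace's dilation speeds and
#' removes samples whose speed exceeds the threshold. Run per eye, before the
#' two eyes are merged.
#'
#' @param trace data frame with `t`, `p`.
#' @param n outlier scalar.
#' @return The filtered trace.
#' @export
mad_outlier_filter <- function(trace, n = 1.5) {
  if (nrow(trace) < 3) {
    warning("fewer than 3 samples; outlier filter skipped")
    return(trace)
  }
  s <- dilation_speed(trace$t, trace$p)
  thr <- speed_outlier_threshold(s, n)$threshold
  out <- trace[s <= thr, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge the left- and right-eye pupil traces
#'
#' Keeps only timestamps at which both eyes survived their per-eye filtering
#' and averages the two diameters.
#'
#' @param left,right data frames with `t`, `p`.
#' @return Merged data frame with `t`, `p`.
#' @export
merge_eyes <- function(left, right) {
  common <- intersect(left$t, right$t)
  if (!length(common)) {
    warning("no common timestamps between eyes")
    return(data.frame(t = numeric(0), p = numeric(0)))
  }
  common <- sort(common)
  pl <- left$p[match(common, left$t)]
  pr <- right$p[match(common, right$t)]
  data.frame(t = common, p = (pl + pr) / 2)
}

#' Resample and smooth a pupil trace onto a uniform grid
#'
#' Produces a uniform 500 Hz (2 ms) sequence from the nonuniformly sampled
#' merged trace. Each output value is a timestamp-weighted exponential moving
#' average (half-life `half_life_ms`) over at most the `window` nearest
#' preceding input samples. Data gaps of `max_gap_ms` or more split the trace
#' into segments: no value is synthesized inside or across a gap.
#'
#' @param trace data frame with `t`, `p`.
#' @param rate_hz output rate.
#' @param window maximum number of preceding samples entering the average.
#' @param half_life_ms exponential decay half-life in ms.
#' @param max_gap_ms gap length at or above which the trace is split.
#' @return Data frame with uniform `t` (within segments) and smoothed `p`.
#' @export
resample_smooth <- function(trace, rate_hz = 500, window = 20,
                            half_life_ms = 10, max_gap_ms = 50) {
  if (!nrow(trace)) return(data.frame(t = numeric(0), p = numeric(0)))
  t_in <- trace$t
  p_in <- trace$p
  step <- 1000 / rate_hz
  n_in <- length(t_in)
  seg <- cumsum(c(TRUE, diff(t_in) >= max_gap_ms))
  t_grid <- seq(t_in[1], t_in[n_in], by = step)
  idx <- findInterval(t_grid, t_in)
  ## a grid point is emitted only inside a segment: between two samples of
  ## the same segment, or exactly on a sample; never inside/through a gap
  interior <- c(seg[-1] == seg[-n_in], FALSE)
  keep <- idx >= 1 &
    (abs(t_grid - t_in[pmax(idx, 1)]) < 1e-9 | interior[pmax(idx, 1)])
  t_grid <- t_grid[keep]
  idx <- idx[keep]
  if (!length(t_grid)) return(data.frame(t = numeric(0), p = numeric(0)))
  lam <- log(2) / half_life_ms
  num <- numeric(length(t_grid))
  den <- numeric(length(t_grid))
  seg_at <- seg[idx]
  for (k in 0:(window - 1)) {
    j <- idx - k
    use <- j >= 1
    jj <- pmax(j, 1)
    use <- use & seg[jj] == seg_at
    w <- exp(-lam * (t_grid - t_in[jj]))
    w[!use] <- 0
    num <- num + w * p_in[jj]
    den <- den + w
  }
  data.frame(t = t_grid, p = num / den)
}

#' Summary statistics of a preprocessed pupil trace
#'
#' The four per-trial pupil biomarkers: average, maximum, minimum and
#' standard deviation (sample, n-1 denominator) of the uniform diameter
#' sequence.
#'
#' @param trace data frame with `p` (mm), or a numeric vector.
#' @return Named list `D_Pupil_Avg`, `D_Pupil_Max`, `D_Pupil_Min`,
#'   `D_Pupil_Sd`; all `NA` for an empty trace.
#' @export
pupil_metrics <- function(trace) {
  p <- if (is.data.frame(trace)) trace$p else trace
  if (!length(p)) {
    return(list(D_Pupil_Avg = NA_real_, D_Pupil_Max = NA_real_,
                D_Pupil_Min = NA_real_, D_Pupil_Sd = NA_real_))
  }
  list(D_Pupil_Avg = mean(p),
       D_Pupil_Max = max(p),
       D_Pupil_Min = min(p),
       D_Pupil_Sd = if (length(p) > 1) stats::sd(p) else 0)
}

#' Full per-trial pupil preprocessing pipeline
#'
#' Runs the five preprocessing steps on one trial's raw samples: (1) per-eye
#' validity and feasible-range filtering, (2) per-eye dilation-speed outlier
#' rejection, (3) binocular merge, (4) uniform resampling with exponential
#' smoothing, (5) summary metrics.
#'
#' @param samples gaze-sample data frame (dialect columns) for one trial.
#' @param range_mm feasible diameter range.
#' @param mad_scalar outlier scalar `n`.
#' @param rate_hz,window,half_life_ms,max_gap_ms see [resample_smooth()].
#' @return List with `metrics` (see [pupil_metrics()]) and the resampled
#'   `trace`.
#' @export
preprocess_pupil <- function(samples, range_mm = c(1.5, 9.0), mad_scalar = 1.5,
                             rate_hz = 500, window = 20, half_life_ms = 10,
                             max_gap_ms = 50) {
  eye <- function(p, valid) {
    tr <- data.frame(t = samples$timestamp_ms, p = p, valid = valid)
    tr <- suppressWarnings(range_filter(tr, range_mm))
    suppressWarnings(mad_outlier_filter(tr, mad_scalar))
  }
  left <- eye(samples$pupil_left_mm, samples$valid_left)
  right <- eye(samples$pupil_right_mm, samples$valid_right)
  merged <- suppressWarnings(merge_eyes(left, right))
  uni <- resample_smooth(merged, rate_hz, window, half_life_ms, max_gap_ms)
  list(metrics = pupil_metrics(uni), trace = uni)
}
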