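test_that("feasible-range filter keeps the closed interval 1.5-9.0 mm", {
  tr <- data.frame(t = c(0, 10, 20), p = c(3.0, 0.9, 3.1))
  expect_equal(range_filter(tr)$p, c(3.0, 3.1))
  tr2 <- data.frame(t = c(0, 10), p = c(9.0, 1.5))
  expect_equal(range_filter(tr2)$p, c(9.0, 1.5))  # inclusive bounds
  expect_warning(out <- range_filter(data.frame(t = 0:2, p = rep(12, 3))),
                 "removed every sample")
  expect_equal(nrow(out), 0)
  # invalid-flagged samples are removed even when in range
  tr3 <- data.frame(t = c(0, 10), p = c(3, 3), valid = c(1, 0))
  expect_equal(nrow(range_filter(tr3)), 1)
  # idempotence
  once <- range_filter(tr)
  expect_equal(range_filter(once), once)
})

test_that("dilation speed takes the two-sided max, one-sided at endpoints", {
  expect_equal(dilation_speed(c(0, 10, 20), c(3, 3, 3)), c(0, 0, 0))
  s <- dilation_speed(c(0, 10, 20), c(3.0, 3.1, 3.0))
  expect_equal(s[2], 0.01)
  s2 <- dilation_speed(c(0, 10, 20), c(3.0, 3.1, 3.3))
  expect_equal(s2, c(0.01, 0.02, 0.02))  # endpoint uses its one side
  expect_error(dilation_speed(c(0, 0, 10), c(1, 2, 3)),
               "strictly increasing")
})

test_that("MAD threshold reproduces the worked speed example", {
  thr <- speed_outlier_threshold(c(1, 2, 100), n = 1.5)
  expect_equal(thr$median, 2)
  expect_equal(thr$mad, 1)
  expect_equal(thr$threshold, 3.5)
  # constant speeds: MAD 0, threshold = median, nothing removed
  thr0 <- speed_outlier_threshold(rep(0.5, 10))
  expect_equal(thr0$threshold, 0.5)
  tr <- data.frame(t = seq(0, 90, by = 10), p = rep(3, 10))
  expect_equal(nrow(mad_outlier_filter(tr)), 10)
})

test_that("MAD matches a brute-force median implementation on random traces", {
  brute_median <- function(v) {
    v <- sort(v); n <- length(v)
    if (n %% 2 == 1) v[(n + 1) / 2] else (v[n / 2] + v[n / 2 + 1]) / 2
  }
  set.seed(42)
  for (i in 1:1000) {
    s <- abs(rnorm(sample(3:40, 1), sd = runif(1, 0.001, 1)))
    got <- speed_outlier_threshold(s)
    med <- brute_median(s)
    mad <- brute_median(abs(s - med))
    expect_equal(got$median, med, tolerance = 1e-12)
    expect_equal(got$mad, mad, tolerance = 1e-12)
    expect_equal(got$threshold, med + 1.5 * mad, tolerance = 1e-12)
  }
})

test_that("outlier removal shrinks as the scalar n grows", {
  set.seed(1)
  t <- cumsum(runif(200, 2, 6))
  p <- 4 + cumsum(rnorm(200, 0, 0.01))
  p[sample(200, 10)] <- p[sample(200, 10)] + 1
  sizes <- vapply(c(0.5, 1, 1.5, 2, 3, 5),
                  function(n) nrow(mad_outlier_filter(data.frame(t = t, p = p),
                                                      n)), 0)
  expect_true(all(diff(sizes) >= 0))
})

test_that("eye merging keeps common timestamps and averages diameters", {
  left <- data.frame(t = c(0, 10, 20), p = c(3.0, 3.0, 3.0))
  right <- data.frame(t = c(10, 20, 30), p = c(3.2, 3.4, 3.6))
  m <- merge_eyes(left, right)
  expect_equal(m$t, c(10, 20))
  expect_equal(m$p, c(3.1, 3.2))
  expect_equal(merge_eyes(left, left), left)
  expect_warning(m0 <- merge_eyes(left, data.frame(t = 99, p = 3)),
                 "no common")
  expect_equal(nrow(m0), 0)
})

test_that("resampling emits a 2 ms grid and never bridges long gaps", {
  t <- c(seq(0, 100, by = 7), seq(160, 260, by = 7))  # 60 ms gap
  tr <- data.frame(t = t, p = rep(3, length(t)))
  out <- resample_smooth(tr)
  expect_equal(out$p, rep(3, nrow(out)))  # smoothing preserves constants
  expect_false(any(out$t > 100 + 49 & out$t < 160))  # nothing inside the gap
  d <- diff(out$t)
  expect_true(all(abs(d[d < 50] - 2) < 1e-9))  # 500 Hz within segments
})

test_that("pupil summary metrics have the declared denominators and bounds", {
  m <- pupil_metrics(rep(3, 10))
  expect_equal(unlist(m[c("D_Pupil_Avg", "D_Pupil_Max", "D_Pupil_Min")]),
               c(D_Pupil_Avg = 3, D_Pupil_Max = 3, D_Pupil_Min = 3))
  expect_equal(m$D_Pupil_Sd, 0)
  m2 <- pupil_metrics(c(2, 4))
  expect_equal(m2$D_Pupil_Avg, 3)
  expect_equal(m2$D_Pupil_Sd, sd(c(2, 4)))  # sample (n-1) denominator
  expect_true(is.na(pupil_metrics(numeric(0))$D_Pupil_Avg))
  set.seed(2)
  for (i in 1:200) {
    p <- runif(sample(2:50, 1), 2, 8)
    m <- pupil_metrics(p)
    expect_true(m$D_Pupil_Min <= m$D_Pupil_Avg && m$D_Pupil_Avg <= m$D_Pupil_Max)
  }
})

test_that("the full pipeline never emits diameters outside 1.5-9.0 mm", {
  set.seed(33)
  for (i in 1:1000) {
    n <- sample(10:60, 1)
    ts <- cumsum(runif(n, 2, 8))
    p <- runif(n, 0.5, 11)  # deliberately includes infeasible values
    smp <- data.frame(timestamp_ms = ts,
                      pupil_left_mm = p + rnorm(n, 0, 0.05),
                      pupil_right_mm = p + rnorm(n, 0, 0.05),
                      valid_left = 1L, valid_right = 1L)
    out <- preprocess_pupil(smp)
    if (nrow(out$trace)) {
      expect_true(all(out$trace$p >= 1.5 - 1e-9 & out$trace$p <= 9 + 1e-9))
    }
  }
})

test_that("injected spikes are removed while clean samples survive", {
  set.seed(99)
  n <- 1000
  ts <- seq(0, by = 4, length.out = n)
  p <- 3 + 2^-12 * ts  # smooth signal: exactly constant dilation speed
  spikes <- sort(sample(seq(10, n - 10, by = 25), 15))
  p[spikes] <- p[spikes] + 0.3
  tr <- data.frame(t = ts, p = p)
  s <- dilation_speed(ts, p)
  thr <- speed_outlier_threshold(s)
  expect_gt(0.3 / 4, 10 * max(thr$mad, 1e-6))  # spikes dwarf the MAD scale
  out <- mad_outlier_filter(tr)
  expect_lt(sum(out$t %in% ts[spikes]) / length(spikes), 0.05)  # >95% removed
  clean <- setdiff(ts, ts[spikes])
  expect_gt(sum(out$t %in% clean) / length(clean), 0.95)  # <=5% clean lost
})
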