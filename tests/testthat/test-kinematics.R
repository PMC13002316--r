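make_sine_traj <- function(freq_hz, n = 401, fs = 200) {
  t <- seq(0, by = 1 / fs, length.out = n)
  data.frame(t_s = t, x_cm = sin(2 * pi * freq_hz * t), y_cm = 0)
}

test_that("low-pass filter preserves DC and low frequencies, kills high ones", {
  dc <- data.frame(t_s = seq(0, 2, by = 0.005), x_cm = 3.7, y_cm = -1.2)
  f <- filter_trajectory(dc)
  expect_lt(max(abs(f$x_cm - 3.7)), 0.01)
  expect_lt(max(abs(f$y_cm + 1.2)), 0.01)
  expect_equal(f$t_s, dc$t_s)

  lo <- make_sine_traj(1)
  flo <- filter_trajectory(lo)
  mid <- 100:300
  expect_gt(max(abs(flo$x_cm[mid])) / max(abs(lo$x_cm[mid])), 0.99)

  hi <- make_sine_traj(50)
  fhi <- filter_trajectory(hi)
  expect_lt(max(abs(fhi$x_cm[mid])) / max(abs(hi$x_cm[mid])), 0.01)
})

test_that("filter rejects too-short input and bad cutoffs", {
  short <- data.frame(t_s = seq(0, 0.05, by = 0.005), x_cm = 0, y_cm = 0)
  expect_error(filter_trajectory(short), "too short")
  ok <- make_sine_traj(1)
  expect_error(filter_trajectory(ok, cutoff_hz = 150), "Nyquist")
})

test_that("rotation to the common axis is the expected rigid motion", {
  tr <- data.frame(t_s = c(0, 1), x_cm = c(0, 5), y_cm = c(0, 0))
  # 90-degree target: identity
  r90 <- rotate_to_common_axis(tr, 90)
  expect_equal(r90$x_cm, tr$x_cm)
  # 0-degree target: (5, 0) maps onto (0, 5)
  r0 <- rotate_to_common_axis(tr, 0)
  expect_equal(r0$x_cm[2], 0, tolerance = 1e-12)
  expect_equal(r0$y_cm[2], 5, tolerance = 1e-12)
  # isometry on an arbitrary path
  set.seed(3)
  path <- data.frame(t_s = 1:20, x_cm = rnorm(20), y_cm = rnorm(20))
  rot <- rotate_to_common_axis(path, 270)
  d0 <- dist(cbind(path$x_cm, path$y_cm))
  d1 <- dist(cbind(rot$x_cm, rot$y_cm))
  expect_lt(max(abs(d0 - d1)), 1e-9)
})

test_that("event detection uses strict threshold crossings", {
  # speed ramp: exactly at threshold, then above
  t <- seq(0, 0.5, by = 0.005)
  v <- c(rep(0, 50), rep(1, 10), rep(3, 41))  # cm/s segments
  x <- cumsum(v) * 0.005
  tr <- data.frame(t_s = t, x_cm = x, y_cm = 0)
  ev <- detect_events(tr, onset_speed_cm_s = 1, offset_radius_cm = 0.2)
  sp <- c(0, diff(x) / 0.005)
  expect_gt(max(sp[ev$onset_index + (-1:1)]), 1)  # strictly exceeding region
  still <- data.frame(t_s = t, x_cm = 0, y_cm = 0)
  ev0 <- detect_events(still)
  expect_false(ev0$complete)
  expect_true(is.na(ev0$onset_index))
})

test_that("hand angle sign convention is clockwise-positive", {
  mk <- function(off_x, off_y) {
    data.frame(t_s = c(0, 1), x_cm = c(0, off_x), y_cm = c(0, off_y))
  }
  # offset exactly on target
  expect_equal(compute_hand_angle(mk(0, 5), 1, 2, c(0, 5)), 0)
  # 10 degrees clockwise of the 90-degree target
  expect_equal(compute_hand_angle(mk(5 * sinpi(10 / 180),
                                     5 * cospi(10 / 180)), 1, 2, c(0, 5)),
               10, tolerance = 1e-9)
  # counterclockwise quarter turn
  expect_equal(compute_hand_angle(mk(-5, 0), 1, 2, c(0, 5)), -90)
  expect_error(compute_hand_angle(mk(0, 0), 1, 2, c(0, 5)), "zero-length")
})

test_that("straightness is chord over path length", {
  straight <- data.frame(t_s = 0:10, x_cm = 0, y_cm = seq(0, 5, length.out = 11))
  expect_equal(straightness(straight, 1, 11), 1)
  # half circle: chord / arc = 2 / pi
  th <- seq(0, pi, length.out = 400)
  half <- data.frame(t_s = seq_along(th), x_cm = cos(th), y_cm = sin(th))
  expect_equal(straightness(half, 1, 400), 2 / pi, tolerance = 1e-4)
  set.seed(5)
  wig <- data.frame(t_s = 1:50, x_cm = cumsum(rnorm(50)), y_cm = cumsum(rnorm(50)))
  expect_lte(straightness(wig, 1, 50), 1)
})

test_that("each exclusion criterion flags exactly its violation", {
  n <- 60
  set.seed(8)
  base <- data.frame(hand_angle_deg = rnorm(n, 2, 3),
                     rt_ms = rnorm(n, 440, 30),
                     mt_ms = rnorm(n, 184, 15),
                     amplitude_cm = rep(6, n))
  base$hand_angle_deg[10] <- 95        # beyond +/- 90
  base$hand_angle_deg[20] <- 40        # > 25 deg from moving median
  base$mt_ms[30] <- 600                # MT limit
  base$amplitude_cm[40] <- 4.2         # amplitude
  ex <- apply_exclusions(base)
  expect_true(ex$excl_angle_outlier[10])
  expect_true(ex$excl_angle_outlier[20])
  expect_true(ex$excl_mt_limit[30])
  expect_true(ex$excl_amplitude[40])
  expect_match(ex$exclusion_reasons[30], "mt_limit")
  clean <- setdiff(seq_len(n), c(10, 20, 30, 40))
  expect_false(any(ex$excl_mt_limit[clean]))
  expect_false(any(ex$excl_amplitude[clean]))
  expect_false(any(ex$excl_angle_outlier[clean]))
  expect_true(all(ex$excluded == (ex$exclusion_reasons != "")))
})

test_that("KDE-based RT criterion flags the gross outlier and matches a brute-force recheck", {
  set.seed(2)
  rts <- c(rnorm(100, 440, 30), 2000)
  tr <- data.frame(hand_angle_deg = rnorm(101, 2, 3), rt_ms = rts,
                   mt_ms = rnorm(101, 184, 10), amplitude_cm = 6)
  ex <- apply_exclusions(tr)
  thr <- attr(ex, "rt_threshold_ms")
  # flagged set is exactly the trials above the threshold, recomputed by
  # brute-force inversion of the same Gaussian-KDE mixture CDF
  grid <- seq(min(rts) - 100, max(rts) + 100, length.out = 20000)
  bw <- bw.nrd0(rts)
  cdf <- rowMeans(pnorm(outer(grid, rts, "-") / bw))
  thr_bf <- grid[which(cdf >= 0.975)[1]]
  expect_equal(thr, thr_bf, tolerance = 0.01)
  expect_equal(which(ex$excl_rt_outlier), which(rts > thr_bf))
  # here the bulk sits below the threshold, so only the outlier is flagged
  expect_equal(sum(ex$excl_rt_outlier), 1)
  expect_true(ex$excl_rt_outlier[101])
  expect_lt(thr, 2000)
})

test_that("few-trial RT criterion falls back to the empirical percentile", {
  tr <- data.frame(hand_angle_deg = rnorm(10, 0, 2),
                   rt_ms = c(rep(400, 9), 1500),
                   mt_ms = rep(180, 10), amplitude_cm = 6)
  expect_warning(ex <- apply_exclusions(tr), "fewer than 20")
  expect_s3_class(ex, "data.frame")
})

test_that("loosening thresholds never excludes more trials", {
  set.seed(13)
  n <- 120
  tr <- data.frame(hand_angle_deg = rnorm(n, 2, 12),
                   rt_ms = rlnorm(n, log(430), 0.25),
                   mt_ms = rnorm(n, 250, 120),
                   amplitude_cm = runif(n, 4.5, 7))
  strict <- apply_exclusions(tr, mt_limit_ms = 400, angle_limit_deg = 60,
                             median_dev_deg = 15, min_amplitude_cm = 5.5,
                             rt_percentile = 0.9)
  loose <- apply_exclusions(tr, mt_limit_ms = 500, angle_limit_deg = 90,
                            median_dev_deg = 25, min_amplitude_cm = 5,
                            rt_percentile = 0.975)
  expect_true(all(which(loose$excluded) %in% which(strict$excluded)))
})

test_that("cycle aggregation averages valid trials and baseline-adjusts", {
  tr <- data.frame(cycle = rep(1:12, each = 4),
                   hand_angle_deg = 2, excluded = FALSE)
  cs <- aggregate_and_adjust(tr)
  expect_equal(cs$hand_angle, rep(0, 12))
  expect_equal(attr(cs, "baseline_offset_deg"), 2)

  tr2 <- data.frame(cycle = rep(1, 4), hand_angle_deg = c(1, 2, 3, 4),
                    excluded = c(FALSE, FALSE, FALSE, FALSE))
  expect_equal(aggregate_and_adjust(tr2, baseline_cycles = 1)$hand_angle +
                 attr(aggregate_and_adjust(tr2, baseline_cycles = 1),
                      "baseline_offset_deg"), 2.5)
  tr2$excluded[4] <- TRUE
  cs2 <- aggregate_and_adjust(tr2, baseline_cycles = 1, adjust = FALSE)
  expect_equal(cs2$hand_angle, 2)
  expect_equal(cs2$n_valid, 3L)
})

test_that("baseline adjustment is invariant to constant shifts and zeroes the baseline", {
  set.seed(17)
  tr <- data.frame(cycle = rep(1:20, each = 4),
                   hand_angle_deg = rnorm(80, 3, 2), excluded = FALSE)
  cs <- aggregate_and_adjust(tr)
  expect_equal(mean(cs$hand_angle[cs$cycle %in% 6:10]), 0, tolerance = 1e-12)
  tr_shift <- tr
  tr_shift$hand_angle_deg <- tr$hand_angle_deg + 7.3
  expect_equal(aggregate_and_adjust(tr_shift)$hand_angle, cs$hand_angle,
               tolerance = 1e-12)
})

test_that("cycles with no valid trial become flagged missing values", {
  tr <- data.frame(cycle = rep(1:10, each = 4),
                   hand_angle_deg = 1, excluded = FALSE)
  tr$excluded[tr$cycle == 4] <- TRUE
  cs <- aggregate_and_adjust(tr)
  expect_true(is.na(cs$hand_angle[4]))
  expect_equal(attr(cs, "empty_cycles"), 4)
})

test_that("clamp-direction adjustment mirrors clockwise-clamp participants", {
  expect_equal(adjust_for_clamp(c(5, -3), -1), c(5, -3))
  expect_equal(adjust_for_clamp(c(5, -3), 1), c(-5, 3))
})
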