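#' Low-pass filter a trajectory
#'
#' Zero-phase (forward-backward) Butterworth low-pass filtering of the x and
#' y position signals; the default is an 8th-order filter with a 10 Hz
#' cutoff. Forward-backward application removes phase lag (so event times
#' are not shifted) at the cost of doubling the effective order. The signal
#' is odd-reflection padded before filtering to suppress boundary
#' transients.
#'
#' @param traj data.frame with columns `t_s`, `x_cm`, `y_cm`, uniformly
#'   sampled.
#' @param cutoff_hz cutoff frequency (must be below Nyquist).
#' @param order filter order.
#' @return the trajectory with filtered `x_cm`, `y_cm` (same length and
#'   time base).
#' @export
filter_trajectory <- function(traj, cutoff_hz = 10, order = 8) {
  stopifnot(is.data.frame(traj), all(c("t_s", "x_cm", "y_cm") %in% names(traj)))
  n <- nrow(traj)
  if (n < 3 * order) {
    stop(sprintf("trajectory too short to filter (%d samples < %d)",
                 n, 3 * order))
  }
  dt <- stats::median(diff(traj$t_s))
  fs <- 1 / dt
  if (cutoff_hz >= fs / 2) stop("cutoff at or above Nyquist frequency")
  bf <- signal::butter(order, cutoff_hz / (fs / 2))

  pad <- min(n - 1L, 100L)
  smooth1 <- function(v) {
    vp <- c(2 * v[1] - rev(v[2:(pad + 1)]),
            v,
            2 * v[n] - rev(v[(n - pad):(n - 1)]))
    signal::filtfilt(bf, vp)[(pad + 1):(pad + n)]
  }
  out <- traj
  out$x_cm <- smooth1(traj$x_cm)
  out$y_cm <- smooth1(traj$y_cm)
  out
}

#' Rotate a trajectory to the common (90 degree) axis
#'
#' Rigid rotation taking the trial's target direction onto the 90-degree
#' (12 o'clock) axis, so that all trials share a common reference frame
#' with the target at (0, target distance).
#'
#' @param traj trajectory data.frame (`t_s`, `x_cm`, `y_cm`).
#' @param target_direction_deg the trial's target direction, one of
#'   0, 90, 180, 270.
#' @return rotated trajectory.
#' @export
rotate_to_common_axis <- function(traj, target_direction_deg) {
  stopifnot(target_direction_deg %in% c(0, 90, 180, 270))
  phi <- (90 - target_direction_deg) / 180  # turns of pi
  c_ <- cospi(phi)
  s_ <- sinpi(phi)
  out <- traj
  out$x_cm <- c_ * traj$x_cm - s_ * traj$y_cm
  out$y_cm <- s_ * traj$x_cm + c_ * traj$y_cm
  out
}

# central-difference speed (cm/s); endpoints use one-sided differences
traj_speed <- function(traj) {
  n <- nrow(traj)
  dt <- stats::median(diff(traj$t_s))
  vx <- c(traj$x_cm[2] - traj$x_cm[1],
          (traj$x_cm[3:n] - traj$x_cm[1:(n - 2)]) / 2,
          traj$x_cm[n] - traj$x_cm[n - 1]) / dt
  vy <- c(traj$y_cm[2] - traj$y_cm[1],
          (traj$y_cm[3:n] - traj$y_cm[1:(n - 2)]) / 2,
          traj$y_cm[n] - traj$y_cm[n - 1]) / dt
  sqrt(vx^2 + vy^2)
}

#' Detect reach onset and offset
#'
#' Onset is the first sample whose speed strictly exceeds the velocity
#' threshold (default 1 cm/s, computed from central differences of the
#' filtered positions); offset is the first subsequent sample whose radial
#' distance from the trial's starting position strictly exceeds the target
#' distance (default 5 cm). Reaction time (RT) is the time from trial start
#' to onset; movement time (MT) from onset to offset.
#'
#' @param traj filtered trajectory.
#' @param onset_speed_cm_s onset speed threshold.
#' @param offset_radius_cm offset radius threshold.
#' @return list with `onset_index`, `offset_index`, `rt_ms`, `mt_ms`,
#'   `complete` (FALSE when the radius is never exceeded, i.e. the movement
#'   amplitude fell short of the target distance).
#' @export
detect_events <- function(traj, onset_speed_cm_s = 1, offset_radius_cm = 5) {
  stopifnot(onset_speed_cm_s > 0, offset_radius_cm > 0)
  sp <- traj_speed(traj)
  r <- sqrt((traj$x_cm - traj$x_cm[1])^2 + (traj$y_cm - traj$y_cm[1])^2)
  onset <- which(sp > onset_speed_cm_s)[1]
  if (is.na(onset)) {
    return(list(onset_index = NA_integer_, offset_index = NA_integer_,
                rt_ms = NA_real_, mt_ms = NA_real_, complete = FALSE))
  }
  off_rel <- which(r[onset:length(r)] > offset_radius_cm)[1]
  if (is.na(off_rel)) {
    return(list(onset_index = onset, offset_index = NA_integer_,
                rt_ms = (traj$t_s[onset] - traj$t_s[1]) * 1000,
                mt_ms = NA_real_, complete = FALSE))
  }
  offset <- onset + off_rel - 1L
  list(onset_index = onset, offset_index = offset,
       rt_ms = (traj$t_s[onset] - traj$t_s[1]) * 1000,
       mt_ms = (traj$t_s[offset] - traj$t_s[onset]) * 1000,
       complete = TRUE)
}

#' Signed hand angle of a reach
#'
#' Angle between the vector from the reach-onset position to the target
#' center and the vector from the reach-onset position to the reach-offset
#' position, in degrees, positive clockwise, in (-180, 180].
#'
#' @param traj trajectory data.frame.
#' @param onset_index,offset_index event indices from [detect_events()].
#' @param target_xy numeric length-2 target position in the trajectory's
#'   frame.
#' @return signed angle in degrees.
#' @export
compute_hand_angle <- function(traj, onset_index, offset_index, target_xy) {
  u <- c(target_xy[1] - traj$x_cm[onset_index],
         target_xy[2] - traj$y_cm[onset_index])
  v <- c(traj$x_cm[offset_index] - traj$x_cm[onset_index],
         traj$y_cm[offset_index] - traj$y_cm[onset_index])
  if (sqrt(sum(v^2)) < 1e-12) stop("zero-length movement vector: angle undefined")
  ang <- -atan2(u[1] * v[2] - u[2] * v[1], sum(u * v)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Straightness ratio of a reach
#'
#' Straight-line (chord) distance from onset to offset divided by the path
#' length along the trajectory between them; 1 for a perfectly straight
#' reach, 2/pi for a half-circle detour.
#'
#' @inheritParams compute_hand_angle
#' @return ratio in (0, 1].
#' @export
straightness <- function(traj, onset_index, offset_index) {
  idx <- onset_index:offset_index
  seg <- sqrt(diff(traj$x_cm[idx])^2 + diff(traj$y_cm[idx])^2)
  path <- sum(seg)
  if (path < 1e-12) stop("zero path length: straightness undefined")
  chord <- sqrt((traj$x_cm[offset_index] - traj$x_cm[onset_index])^2 +
                (traj$y_cm[offset_index] - traj$y_cm[onset_index])^2)
  min(chord / path, 1)
}

#' Process one raw trial through the kinematic pipeline
#'
#' Filter, rotate to the common axis, detect events, and compute hand
#' angle, RT, MT, total action duration, amplitude and straightness.
#'
#' @param traj raw trajectory (`t_s`, `x_cm`, `y_cm`).
#' @param target_direction_deg the trial's target direction.
#' @param target_cm radial target distance (cm).
#' @param cutoff_hz,order filter settings.
#' @param onset_speed_cm_s onset threshold.
#' @return one-row data.frame of trial kinematics (`hand_angle_deg`,
#'   `rt_ms`, `mt_ms`, `tad_ms`, `amplitude_cm`, `straightness`,
#'   `complete`).
#' @export
process_trajectory <- function(traj, target_direction_deg, target_cm = 5,
                               cutoff_hz = 10, order = 8,
                               onset_speed_cm_s = 1) {
  f <- filter_trajectory(traj, cutoff_hz = cutoff_hz, order = order)
  f <- rotate_to_common_axis(f, target_direction_deg)
  ev <- detect_events(f, onset_speed_cm_s = onset_speed_cm_s,
                      offset_radius_cm = target_cm)
  amp <- max(sqrt((f$x_cm - f$x_cm[1])^2 + (f$y_cm - f$y_cm[1])^2))
  if (!ev$complete) {
    return(data.frame(hand_angle_deg = NA_real_, rt_ms = ev$rt_ms,
                      mt_ms = NA_real_, tad_ms = NA_real_,
                      amplitude_cm = amp, straightness = NA_real_,
                      complete = FALSE))
  }
  ang <- compute_hand_angle(f, ev$onset_index, ev$offset_index,
                            target_xy = c(0, target_cm))
  data.frame(hand_angle_deg = ang, rt_ms = ev$rt_ms, mt_ms = ev$mt_ms,
             tad_ms = ev$rt_ms + ev$mt_ms, amplitude_cm = amp,
             straightness = straightness(f, ev$onset_index, ev$offset_index),
             complete = TRUE)
}

# 97.5th percentile of a Gaussian-KDE-smoothed distribution, by numeric
# inversion of the KDE CDF on a fine grid (Silverman bandwidth)
kde_percentile <- function(x, p = 0.975, n_grid = 4096) {
  d <- stats::density(x, bw = "nrd0", n = n_grid,
                      from = min(x) - 3 * stats::bw.nrd0(x),
                      to = max(x) + 3 * stats::bw.nrd0(x))
  cdf <- cumsum(d$y)
  cdf <- cdf / cdf[length(cdf)]
  d$x[which(cdf >= p)[1]]
}

# centered 10-point moving median (5 before, 4 after, truncated at edges)
moving_median <- function(x, window = 10) {
  n <- length(x)
  half_lo <- ceiling((window - 1) / 2)
  half_hi <- floor((window - 1) / 2)
  vapply(seq_len(n), function(i) {
    idx <- max(1, i - half_lo):min(n, i + half_hi)
    stats::median(x[idx], na.rm = TRUE)
  }, numeric(1))
}

#' Apply the four trial-exclusion criteria
#'
#' Flags trials where (1) movement amplitude is below the target distance;
#' (2) the hand angle exceeds +/- 90 degrees or deviates more than 25
#' degrees from a 10-point moving median (computed in chronological order
#' over trials passing the amplitude and +/-90 checks); (3) RT exceeds the
#' participant's 97.5th percentile, obtained by kernel density estimation
#' (Gaussian kernel, Silverman bandwidth; empirical percentile fallback
#' with a warning below 20 trials); or (4) MT exceeds 500 ms.
#'
#' @param trials data.frame of per-trial kinematics for one participant in
#'   chronological order, with columns `hand_angle_deg`, `rt_ms`, `mt_ms`,
#'   `amplitude_cm` (and optionally `complete`).
#' @param rt_percentile RT exclusion percentile (default 0.975).
#' @param mt_limit_ms MT limit (default 500).
#' @param angle_limit_deg absolute hand-angle limit (default 90).
#' @param median_window moving-median window in trials (default 10).
#' @param median_dev_deg allowed deviation from the moving median
#'   (default 25).
#' @param min_amplitude_cm amplitude criterion (default 5).
#' @return `trials` with added logical columns `excl_amplitude`,
#'   `excl_angle_outlier`, `excl_rt_outlier`, `excl_mt_limit`, `excluded`,
#'   and character `exclusion_reasons`.
#' @export
apply_exclusions <- function(trials, rt_percentile = 0.975,
                             mt_limit_ms = 500, angle_limit_deg = 90,
                             median_window = 10, median_dev_deg = 25,
                             min_amplitude_cm = 5) {
  stopifnot(is.data.frame(trials),
            all(c("hand_angle_deg", "rt_ms", "mt_ms", "amplitude_cm") %in%
                  names(trials)))
  n <- nrow(trials)
  amp_bad <- is.na(trials$amplitude_cm) | trials$amplitude_cm < min_amplitude_cm
  ang <- trials$hand_angle_deg
  hard_ang <- !is.na(ang) & abs(ang) > angle_limit_deg

  # moving median over trials surviving the amplitude and hard-angle checks
  ang_for_med <- ang
  ang_for_med[amp_bad | hard_ang] <- NA
  med <- moving_median(ang_for_med, window = median_window)
  dev_bad <- !is.na(ang) & !is.na(med) & abs(ang - med) > median_dev_deg
  ang_bad <- hard_ang | dev_bad

  rt_ok <- !is.na(trials$rt_ms)
  rts <- trials$rt_ms[rt_ok]
  if (length(rts) >= 20) {
    rt_thr <- kde_percentile(rts, p = rt_percentile)
  } else {
    warning("fewer than 20 trials with RT; using empirical percentile")
    rt_thr <- as.numeric(stats::quantile(rts, rt_percentile, na.rm = TRUE))
  }
  rt_bad <- rt_ok & trials$rt_ms > rt_thr
  rt_bad[is.na(rt_bad)] <- FALSE

  mt_bad <- !is.na(trials$mt_ms) & trials$mt_ms > mt_limit_ms

  reasons <- vapply(seq_len(n), function(i) {
    paste(c(if (amp_bad[i]) "amplitude",
            if (ang_bad[i]) "angle_outlier",
            if (rt_bad[i]) "rt_outlier",
            if (mt_bad[i]) "mt_limit"), collapse = ";")
  }, character(1))

  out <- trials
  out$excl_amplitude <- amp_bad
  out$excl_angle_outlier <- ang_bad
  out$excl_rt_outlier <- rt_bad
  out$excl_mt_limit <- mt_bad
  out$excluded <- amp_bad | ang_bad | rt_bad | mt_bad
  out$exclusion_reasons <- reasons
  attr(out, "rt_threshold_ms") <- rt_thr
  out
}

#' Adjust hand angles for clamp direction
#'
#' Mirrors raw (clockwise-positive) hand angles of participants who
#' experienced a clockwise clamp, so that positive always denotes
#' adaptation away from the clamp.
#'
#' @param hand_angle_deg raw angles.
#' @param clamp_sign -1 (counterclockwise clamp) or +1 (clockwise).
#' @return adjusted angles.
#' @export
adjust_for_clamp <- function(hand_angle_deg, clamp_sign) {
  stopifnot(all(clamp_sign %in% c(-1, 1)))
  -as.numeric(clamp_sign) * hand_angle_deg
}

#' Aggregate trials to a baseline-adjusted cycle series
#'
#' Averages valid (non-excluded) trial hand angles within each cycle, then
#' subtracts the participant's mean over the baseline cycles (default
#' 6-10) from every cycle. Cycles with no valid trial become NA and are
#' flagged.
#'
#' @param trials data.frame with columns `cycle`, `hand_angle_deg` and
#'   `excluded` (from [apply_exclusions()]); angles should already be in
#'   the adjusted (adaptation-positive) convention.
#' @param baseline_cycles cycles defining the baseline offset.
#' @param adjust subtract the baseline offset (default TRUE).
#' @return data.frame of class `cycle_series`: `cycle`, `hand_angle`
#'   (adjusted), `n_valid`; attributes `baseline_offset_deg`, `adjusted`,
#'   `empty_cycles`.
#' @export
aggregate_and_adjust <- function(trials, baseline_cycles = 6:10,
                                 adjust = TRUE) {
  stopifnot(all(c("cycle", "hand_angle_deg") %in% names(trials)))
  excluded <- trials$excluded %||% rep(FALSE, nrow(trials))
  valid <- !excluded & !is.na(trials$hand_angle_deg)
  cyc <- sort(unique(trials$cycle))
  mean_ang <- vapply(cyc, function(cc) {
    v <- trials$hand_angle_deg[trials$cycle == cc & valid]
    if (length(v) == 0) NA_real_ else mean(v)
  }, numeric(1))
  n_valid <- vapply(cyc, function(cc) sum(trials$cycle == cc & valid),
                    integer(1))
  base <- mean(mean_ang[cyc %in% baseline_cycles], na.rm = TRUE)
  out <- data.frame(cycle = cyc,
                    hand_angle = if (adjust) mean_ang - base else mean_ang,
                    n_valid = n_valid)
  attr(out, "baseline_offset_deg") <- base
  attr(out, "adjusted") <- adjust
  attr(out, "empty_cycles") <- cyc[n_valid == 0]
  class(out) <- c("cycle_series", "data.frame")
  out
}
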