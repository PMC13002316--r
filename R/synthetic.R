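#' Group-level specification for synthetic cohorts
#'
#' Describes the population a synthetic cohort is drawn from: group-level
#' means and dispersions of the state-space parameters, their correlation,
#' output noise, set-break decay and an optional engagement profile.
#' Per-participant (A, b) pairs are drawn from a bivariate normal on
#' (logit A, log b) -- which respects the fitting bounds and keeps the
#' correlation interpretable -- and back-transformed; transformed-scale
#' dispersions are delta-method matched so the natural-scale standard
#' deviations approximate `sd_A` and `sd_b`.
#'
#' Output noise is parameterised per trial (degrees of single-reach
#' direction noise). The default of 3.5 degrees is the typical directional
#' variability of a single reach in error-clamp studies; four-trial cycle
#' means then carry about half that (1.75 degrees), and cycle-level
#' simulation uses `noise_sd_deg / 2` accordingly. The participant-level
#' dispersions default to sd_A = 0.05 and sd_b = 0.012, consistent with
#' the wide individual differences in steady-state adaptation seen in
#' clamp cohorts (asymptotes spanning roughly 0.5 to 27 degrees).
#'
#' @param mean_A group mean retention in (0, 1).
#' @param mean_b group mean error sensitivity (> 0).
#' @param corr_Ab correlation of (A, b) on the sampling scale, in [-1, 1].
#' @param sd_A,sd_b natural-scale participant-level dispersions.
#' @param noise_sd_deg per-trial output noise sigma (degrees).
#' @param d set-break decay exponent in [1, 2].
#' @param n_participants cohort size (default 24).
#' @param engagement optional [engagement_profile()].
#' @return object of class `group_spec`.
#' @export
group_spec <- function(mean_A = 0.917, mean_b = 0.020, corr_Ab = 0,
                       sd_A = 0.05, sd_b = 0.012, noise_sd_deg = 3.5,
                       d = 1.5, n_participants = 24, engagement = NULL) {
  stopifnot(mean_A > 0, mean_A < 1, mean_b > 0,
            corr_Ab >= -1, corr_Ab <= 1,
            sd_A >= 0, sd_b >= 0, noise_sd_deg >= 0,
            d >= 1, d <= 2, n_participants >= 1)
  structure(list(mean_A = mean_A, mean_b = mean_b, corr_Ab = corr_Ab,
                 sd_A = sd_A, sd_b = sd_b, noise_sd_deg = noise_sd_deg,
                 d = d, n_participants = as.integer(n_participants),
                 engagement = engagement),
            class = "group_spec")
}

#' Draw per-participant state-space parameters
#'
#' Samples (logit A, log b) from a bivariate normal with the requested
#' correlation, back-transforms, and rejection-resamples any draw outside
#' the fitting bounds, so every participant is representable by the fitting
#' module.
#'
#' @param spec a [group_spec()].
#' @param seed integer seed.
#' @param max_attempts resampling rounds before giving up.
#' @return data.frame with columns `participant`, `A`, `b`, `d` (cycle
#'   level).
#' @export
draw_participants <- function(spec, seed = 1L, max_attempts = 100L) {
  stopifnot(inherits(spec, "group_spec"))
  n <- spec$n_participants
  mu <- c(logit(spec$mean_A), log(spec$mean_b))
  s1 <- spec$sd_A / (spec$mean_A * (1 - spec$mean_A))
  s2 <- spec$sd_b / spec$mean_b
  r <- spec$corr_Ab
  bd <- ss_bounds()

  draw <- function(k) {
    z1 <- stats::rnorm(k)
    z2 <- r * z1 + sqrt(max(0, 1 - r^2)) * stats::rnorm(k)
    cbind(A = inv_logit(mu[1] + s1 * z1), b = exp(mu[2] + s2 * z2))
  }

  with_seed(seed, {
    out <- matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("A", "b")))
    attempts <- 0L
    while (nrow(out) < n) {
      attempts <- attempts + 1L
      if (attempts > max_attempts) {
        stop("could not draw enough in-bounds participants; ",
             "bounds/dispersion combination infeasible")
      }
      cand <- draw(max(n, 2L * (n - nrow(out))))
      ok <- cand[, "A"] >= bd$A[1] & cand[, "A"] <= bd$A[2] &
        cand[, "b"] >= bd$b[1] & cand[, "b"] <= bd$b[2]
      out <- rbind(out, cand[ok, , drop = FALSE])
    }
    out <- out[seq_len(n), , drop = FALSE]
    data.frame(participant = seq_len(n), A = out[, "A"], b = out[, "b"],
               d = spec$d)
  })
}

#' Simulate one participant's behaviour over a schedule
#'
#' Delegates to [simulate_state_space()] at the trial level (cycle-level
#' parameters are converted via A_trial = A_cycle^(1/4),
#' b_trial = b_cycle / 4) and aggregates trial hand angles to cycle means.
#' With `noise_sd = 0` the result equals the deterministic model
#' trajectory exactly.
#'
#' @param schedule a trial-level `clamp_schedule`.
#' @param params list/row with elements `A`, `b`, `d` at cycle level.
#' @param clamp_deg clamp magnitude in degrees.
#' @param noise_sd per-trial output noise sigma (degrees); four-trial
#'   cycle means then have noise about `noise_sd / 2`.
#' @param engagement optional [engagement_profile()].
#' @param seed integer seed.
#' @return list with `trials` (the [simulate_state_space()] output) and
#'   `cycles` (data.frame `cycle`, `hand_angle`, `n_valid`).
#' @export
simulate_behavior <- function(schedule, params, clamp_deg = 45,
                              noise_sd = 0, engagement = NULL,
                              seed = NULL) {
  stopifnot(inherits(schedule, "clamp_schedule"))
  p_tr <- convert_level(
    model_params(params$A, params$b, params$d %||% 1, level = "cycle"),
    to = "trial")
  sim <- simulate_state_space(p_tr, schedule, clamp_deg = clamp_deg,
                              engagement = engagement,
                              noise_sd = noise_sd, seed = seed)
  agg <- stats::aggregate(hand_angle ~ cycle, data = sim, FUN = mean)
  cycles <- data.frame(cycle = agg$cycle, hand_angle = agg$hand_angle,
                       n_valid = as.vector(table(sim$cycle)))
  list(trials = sim, cycles = cycles)
}

#' Simulate a full cohort
#'
#' Draws participants from a group specification and simulates each over
#' its own schedule (clamp direction counterbalanced across participants,
#' fresh within-cycle target orders). Simulation can run at the trial level
#' (default; cycle means aggregated from four trials) or directly at the
#' cycle level.
#'
#' @param spec a [group_spec()].
#' @param group character label attached to the output.
#' @param phases schedule phase lengths, as in [make_schedule()].
#' @param clamp_deg clamp magnitude in degrees.
#' @param level `"trial"` or `"cycle"` simulation granularity.
#' @param seed integer master seed.
#' @return list of class `clamp_cohort` with elements `group`, `truth`
#'   (generating parameters), `schedules`, `cycles` (list of per-participant
#'   cycle data.frames), `trials` (trial-level list or NULL).
#' @export
simulate_cohort <- function(spec, group = "synthetic",
                            phases = c(veridical = 10, clamp = 40, none = 1,
                                       veridical = 20),
                            clamp_deg = 45, level = c("trial", "cycle"),
                            seed = 1L) {
  level <- match.arg(level)
  stopifnot(inherits(spec, "group_spec"))
  truth <- draw_participants(spec, seed = derive_seed(seed, "participants"))
  n <- nrow(truth)
  schedules <- vector("list", n)
  cycles <- vector("list", n)
  trials <- if (level == "trial") vector("list", n) else NULL
  for (i in seq_len(n)) {
    sgn <- if (i %% 2 == 1) -1L else 1L   # counterbalanced clamp direction
    sch <- make_schedule(phases, clamp_sign = sgn,
                         seed = derive_seed(seed, paste0("schedule", i)))
    schedules[[i]] <- sch
    si <- derive_seed(seed, paste0("behavior", i))
    if (level == "trial") {
      beh <- simulate_behavior(sch, truth[i, ], clamp_deg = clamp_deg,
                               noise_sd = spec$noise_sd_deg,
                               engagement = spec$engagement, seed = si)
      trials[[i]] <- beh$trials
      cycles[[i]] <- beh$cycles
    } else {
      p_cy <- model_params(truth$A[i], truth$b[i], truth$d[i], level = "cycle")
      sim <- simulate_state_space(p_cy, schedule_cycles(sch),
                                  clamp_deg = clamp_deg,
                                  engagement = spec$engagement,
                                  noise_sd = spec$noise_sd_deg / 2, seed = si)
      cycles[[i]] <- data.frame(cycle = sim$cycle, hand_angle = sim$hand_angle,
                                n_valid = 4L)
    }
  }
  structure(list(group = group, spec = spec, truth = truth,
                 schedules = schedules, cycles = cycles, trials = trials,
                 clamp_deg = clamp_deg, level = level, seed = seed),
            class = "clamp_cohort")
}

#' Specification of dual-task report accuracy
#'
#' Epoch-wise probabilities of a correct rapid-serial-visual-presentation
#' (RSVP) target-count report. Reports have three options, so chance is
#' 1/3. Defaults follow the canonical dual-task pattern: baseline 0.72, a
#' sharp drop to 0.53 at clamp onset, partial recovery to 0.66 in early and
#' late learning.
#'
#' @param epoch_accuracies named numeric vector over epochs `baseline`,
#'   `onset`, `early`, `late`, `other`.
#' @param n_options number of response options (default 3).
#' @return object of class `rsvp_spec` with `chance = 1/n_options`.
#' @export
rsvp_spec <- function(epoch_accuracies = c(baseline = 0.72, onset = 0.53,
                                           early = 0.66, late = 0.66,
                                           other = 0.72),
                      n_options = 3L) {
  if (any(epoch_accuracies < 0 | epoch_accuracies > 1)) {
    stop("epoch accuracies must lie in [0, 1]")
  }
  chance <- 1 / n_options
  if (any(epoch_accuracies < chance)) {
    warning("some epoch accuracies below chance (", round(chance, 3), ")")
  }
  structure(list(epoch_accuracies = epoch_accuracies,
                 n_options = as.integer(n_options), chance = chance),
            class = "rsvp_spec")
}

#' Simulate per-trial report correctness
#'
#' Bernoulli correctness per trial at the epoch-specific accuracy of the
#' trial's cycle. Only correctness is generated; the visual stream itself
#' is not simulated, since downstream analysis consumes correct/incorrect
#' counts only.
#'
#' @param schedule a trial-level `clamp_schedule`.
#' @param spec an [rsvp_spec()].
#' @param seed integer seed.
#' @return data.frame `trial`, `cycle`, `epoch`, `correct` (0/1).
#' @export
simulate_rsvp <- function(schedule, spec = rsvp_spec(), seed = 1L) {
  stopifnot(inherits(schedule, "clamp_schedule"), inherits(spec, "rsvp_spec"))
  epoch <- cycle_epochs(schedule$cycle)
  # aftereffect cycles carry no distinct accuracy; treat as "other"
  epoch[epoch == "aftereffect"] <- "other"
  p <- spec$epoch_accuracies[epoch]
  if (anyNA(p)) stop("epoch without an accuracy: ",
                     paste(unique(epoch[is.na(p)]), collapse = ", "))
  correct <- with_seed(seed, stats::rbinom(length(p), 1L, p))
  data.frame(trial = schedule$trial, cycle = schedule$cycle, epoch = epoch,
             correct = correct, stringsAsFactors = FALSE)
}

#' Kinematic configuration for trajectory generation
#'
#' @param sample_rate_hz sampling rate (default 200 Hz).
#' @param target_cm radial target distance (default 5 cm).
#' @param amplitude_cm total movement amplitude; shooting movements pass
#'   through the target, so the default 6 cm overshoots it.
#' @param rt_mean_ms,rt_sd_ms reaction-time distribution (normal, truncated
#'   at 100 ms).
#' @param mt_mean_ms,mt_sd_ms movement-time distribution (time from onset to
#'   crossing the target distance; truncated at 155 ms: faster reaches are
#'   smeared so strongly by the 10 Hz low-pass filter that their detected
#'   event times no longer reflect the programmed ones).
#' @param noise_sd_cm additive Gaussian positional noise per sample.
#' @param hold_ms stationary tail recorded after the movement.
#' @param onset_speed_cm_s the onset-detection speed threshold the
#'   requested RT is timed against (default 1 cm/s, matching the event
#'   detector).
#' @return object of class `traj_config`.
#' @export
traj_config <- function(sample_rate_hz = 200, target_cm = 5,
                        amplitude_cm = 6, rt_mean_ms = 440, rt_sd_ms = 50,
                        mt_mean_ms = 184, mt_sd_ms = 20, noise_sd_cm = 0,
                        hold_ms = 100, onset_speed_cm_s = 1) {
  stopifnot(sample_rate_hz > 0, target_cm > 0, amplitude_cm > 0,
            onset_speed_cm_s > 0)
  structure(list(sample_rate_hz = sample_rate_hz, target_cm = target_cm,
                 amplitude_cm = amplitude_cm, rt_mean_ms = rt_mean_ms,
                 rt_sd_ms = rt_sd_ms, mt_mean_ms = mt_mean_ms,
                 mt_sd_ms = mt_sd_ms, noise_sd_cm = noise_sd_cm,
                 hold_ms = hold_ms, onset_speed_cm_s = onset_speed_cm_s),
            class = "traj_config")
}

# time fraction at which a minimum-jerk profile covers fraction `frac` of
# its amplitude; s(tau) = 10 tau^3 - 15 tau^4 + 6 tau^5
minjerk_tau_at <- function(frac) {
  stopifnot(frac > 0, frac < 1)
  stats::uniroot(function(tau) 10 * tau^3 - 15 * tau^4 + 6 * tau^5 - frac,
                 c(1e-9, 1 - 1e-9), tol = 1e-12)$root
}

# early time fraction at which min-jerk speed v(tau) = 30 tau^2 (1-tau)^2
# (peak-normalised to amplitude/duration) reaches `speed`; NA if never
minjerk_tau_speed <- function(speed, amplitude, duration) {
  c_ <- speed * duration / amplitude
  if (c_ >= 30 * 0.5^2 * 0.5^2) return(NA_real_)
  stats::uniroot(function(tau) 30 * tau^2 * (1 - tau)^2 - c_,
                 c(1e-12, 0.5), tol = 1e-12)$root
}

#' Generate raw 2-D reach trajectories
#'
#' Produces per-trial stylus paths from requested hand angles: a stationary
#' pre-movement segment of the requested reaction time, then a straight
#' minimum-jerk reach of `amplitude_cm` along the target direction rotated
#' clockwise by the requested (raw-convention) hand angle, timed so the
#' target distance is crossed at the requested movement time, plus optional
#' positional noise. Passing such a trajectory through the kinematics
#' pipeline with default settings recovers the requested angle to within
#' 0.5 degrees and RT/MT to within one sample.
#'
#' @param trials data.frame with columns `target_deg` and `hand_angle_raw`
#'   (clockwise-positive, degrees); optional `rt_ms`, `mt_ms`,
#'   `amplitude_cm` per trial override the config distributions.
#' @param config a [traj_config()].
#' @param seed integer seed (RT/MT draws and positional noise).
#' @return list of trajectory data.frames (`t_s`, `x_cm`, `y_cm`), each
#'   carrying its requested parameters in attribute `meta`.
#' @export
simulate_trajectories <- function(trials, config = traj_config(), seed = 1L) {
  stopifnot(is.data.frame(trials),
            all(c("target_deg", "hand_angle_raw") %in% names(trials)))
  n <- nrow(trials)
  dt <- 1 / config$sample_rate_hz

  with_seed(seed, {
    rt <- trials$rt_ms %||%
      pmax(100, stats::rnorm(n, config$rt_mean_ms, config$rt_sd_ms))
    mt <- trials$mt_ms %||%
      pmax(155, stats::rnorm(n, config$mt_mean_ms, config$mt_sd_ms))
    amp <- trials$amplitude_cm %||% rep(config$amplitude_cm, n)

    lapply(seq_len(n), function(i) {
      if (mt[i] / 1000 < 3 * dt) {
        stop(sprintf("trial %d: movement time %.0f ms spans fewer than 3 samples",
                     i, mt[i]))
      }
      # movement direction: target direction rotated clockwise by the angle
      dir_deg <- trials$target_deg[i] - trials$hand_angle_raw[i]
      ux <- cospi(dir_deg / 180)
      uy <- sinpi(dir_deg / 180)
      # RT/MT are defined against the event detector: the speed threshold
      # is crossed at rt and the target radius at rt + mt, so the
      # kinematic round trip recovers the requested values. The total
      # duration and movement start are solved jointly (the threshold
      # crossing time depends on the duration).
      mt_s <- mt[i] / 1000
      if (amp[i] > config$target_cm) {
        tau_star <- minjerk_tau_at(config$target_cm / amp[i])
        t_total <- mt_s / tau_star
        for (it in 1:25) {
          tau_v <- minjerk_tau_speed(config$onset_speed_cm_s, amp[i], t_total)
          if (is.na(tau_v)) break
          t_new <- mt_s / (tau_star - tau_v)
          if (abs(t_new - t_total) < 1e-12) { t_total <- t_new; break }
          t_total <- t_new
        }
      } else {
        t_total <- mt_s
        tau_v <- minjerk_tau_speed(config$onset_speed_cm_s, amp[i], t_total)
      }
      if (is.na(tau_v)) {
        stop(sprintf("trial %d: movement too slow to cross the onset threshold", i))
      }
      t_move <- max(0, rt[i] / 1000 - tau_v * t_total)
      t_end <- t_move + t_total + config$hold_ms / 1000
      t <- seq(0, t_end, by = dt)
      tau <- pmin(pmax((t - t_move) / t_total, 0), 1)
      s <- amp[i] * (10 * tau^3 - 15 * tau^4 + 6 * tau^5)
      x <- s * ux
      y <- s * uy
      if (config$noise_sd_cm > 0) {
        x <- x + stats::rnorm(length(t), 0, config$noise_sd_cm)
        y <- y + stats::rnorm(length(t), 0, config$noise_sd_cm)
      }
      out <- data.frame(t_s = t, x_cm = x, y_cm = y)
      attr(out, "meta") <- list(target_deg = trials$target_deg[i],
                                hand_angle_raw = trials$hand_angle_raw[i],
                                rt_ms = rt[i], mt_ms = mt[i],
                                amplitude_cm = amp[i])
      out
    })
  })
}

#' Write a cohort's trial table as CSV
#'
#' Flat layout: one row per trial with participant, group, schedule fields,
#' simulated hand angle and report correctness.
#'
#' @param cohort a `clamp_cohort` simulated at trial level.
#' @param path output CSV path.
#' @param rsvp optional list of per-participant [simulate_rsvp()] outputs.
#' @return the written data.frame, invisibly.
#' @export
write_trial_table <- function(cohort, path, rsvp = NULL) {
  stopifnot(inherits(cohort, "clamp_cohort"), !is.null(cohort$trials))
  rows <- lapply(seq_along(cohort$trials), function(i) {
    sch <- cohort$schedules[[i]]
    tr <- cohort$trials[[i]]
    r <- rsvp[[i]]
    data.frame(
      participant_id = sprintf("%s_%02d", cohort$group, i),
      group = cohort$group,
      trial = sch$trial,
      cycle = sch$cycle,
      target_deg = sch$target_deg,
      feedback = sch$feedback,
      clamp_sign = sch$clamp_sign,
      post_break = sch$post_break,
      hand_angle_deg = tr$hand_angle,
      rsvp_correct = if (is.null(r)) NA_integer_ else r$correct,
      rsvp_epoch = if (is.null(r)) NA_character_ else r$epoch,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}
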