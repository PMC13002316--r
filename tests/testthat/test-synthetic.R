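test_that("degenerate dispersion gives identical participants", {
  gs <- group_spec(mean_A = 0.9, mean_b = 0.02, sd_A = 0, sd_b = 0,
                   n_participants = 8)
  pp <- draw_participants(gs, seed = 1)
  expect_equal(pp$A, rep(0.9, 8), tolerance = 1e-12)
  expect_equal(pp$b, rep(0.02, 8), tolerance = 1e-12)
})

test_that("sampled (A, b) correlation converges to its target", {
  gs0 <- group_spec(mean_A = 0.9, mean_b = 0.025, corr_Ab = 0,
                    sd_A = 0.03, sd_b = 0.006, n_participants = 10000)
  pp0 <- draw_participants(gs0, seed = 2)
  expect_lt(abs(cor(pp0$A, pp0$b)), 0.03)

  gs1 <- group_spec(mean_A = 0.897, mean_b = 0.026, corr_Ab = -0.68,
                    sd_A = 0.03, sd_b = 0.006, n_participants = 10000)
  pp1 <- draw_participants(gs1, seed = 3)
  expect_equal(cor(pp1$A, pp1$b), -0.68, tolerance = 0.03)
})

test_that("all sampled participants respect the fitting bounds", {
  gs <- group_spec(mean_A = 0.95, mean_b = 0.03, sd_A = 0.1, sd_b = 0.03,
                   n_participants = 5000)
  pp <- draw_participants(gs, seed = 4)
  bd <- ss_bounds()
  expect_true(all(pp$A >= bd$A[1] & pp$A <= bd$A[2]))
  expect_true(all(pp$b >= bd$b[1] & pp$b <= bd$b[2]))
})

test_that("noiseless behaviour equals the deterministic model exactly", {
  sch <- default_schedule()
  beh <- simulate_behavior(sch, list(A = 0.92, b = 0.02, d = 1))
  p_tr <- convert_level(model_params(0.92, 0.02), "trial")
  ref <- simulate_state_space(p_tr, sch)
  expect_equal(beh$trials$hand_angle, ref$hand_angle, tolerance = 1e-12)
  # minimal learning at the trial-level b floor stays near zero
  beh0 <- simulate_behavior(sch, list(A = 0.9, b = 0.004))
  p0 <- convert_level(model_params(0.9, 0.004), "trial")
  expect_lte(max(beh0$cycles$hand_angle), steady_state(p0, 45) + 1e-9)
  expect_true(all(beh0$cycles$hand_angle >= 0))
})

test_that("long noiseless run approaches the trial-level closed-form asymptote", {
  sch <- make_schedule(c(veridical = 1, clamp = 300), seed = 1)
  beh <- simulate_behavior(sch, list(A = 0.92, b = 0.02, d = 1))
  p_tr <- convert_level(model_params(0.92, 0.02), "trial")
  expect_equal(tail(beh$trials$hand_angle, 1), steady_state(p_tr, 45),
               tolerance = 1e-6)
})

test_that("behavioural simulation honours the seed contract", {
  sch <- default_schedule()
  p <- list(A = 0.9, b = 0.03, d = 1.3)
  a <- simulate_behavior(sch, p, noise_sd = 3.5, seed = 9)
  b <- simulate_behavior(sch, p, noise_sd = 3.5, seed = 9)
  expect_identical(a, b)
  c_ <- simulate_behavior(sch, p, noise_sd = 3.5, seed = 10)
  expect_false(identical(a$cycles$hand_angle, c_$cycles$hand_angle))
})

test_that("cohort simulation is reproducible and counterbalances clamp sign", {
  gs <- group_spec(n_participants = 4, noise_sd_deg = 3.5)
  co <- simulate_cohort(gs, group = "ST", seed = 5)
  co2 <- simulate_cohort(gs, group = "ST", seed = 5)
  expect_identical(co$cycles, co2$cycles)
  signs <- vapply(co$schedules, function(s)
    s$clamp_sign[s$feedback == "clamp"][1], integer(1))
  expect_equal(signs, c(-1L, 1L, -1L, 1L))
  expect_equal(nrow(co$truth), 4)
})

test_that("rsvp accuracy converges to its epoch rates", {
  sch <- default_schedule()
  # 1,000 simulated participants x 20 baseline trials = 20,000 draws
  correct <- vapply(seq_len(1000), function(k) {
    r <- simulate_rsvp(sch, rsvp_spec(), seed = 1000 + k)
    sum(r$correct[r$epoch == "baseline"])
  }, numeric(1))
  expect_equal(sum(correct) / 20000, 0.72, tolerance = 0.01)
})

test_that("rsvp extremes behave as certainty and chance", {
  sch <- default_schedule()
  all1 <- rsvp_spec(c(baseline = 1, onset = 1, early = 1, late = 1, other = 1))
  r <- simulate_rsvp(sch, all1, seed = 1)
  expect_true(all(r$correct == 1))
  expect_warning(ch <- rsvp_spec(c(baseline = 1/3, onset = 1/3, early = 1/3,
                                   late = 1/3, other = 1/3)), NA)
  expect_equal(ch$chance, 1/3)
  expect_error(rsvp_spec(c(baseline = 1.2, onset = 0.5, early = 0.5,
                           late = 0.5, other = 0.5)), "\\[0, 1\\]")
})

test_that("trajectory round trip recovers requested angle, RT and MT", {
  set.seed(21)
  n <- 40
  # RT/MT from the generator's operating distributions, aligned to the
  # 200 Hz sample grid so the +/- 1 sample contract is exact
  trials <- data.frame(
    target_deg = sample(c(0, 90, 180, 270), n, replace = TRUE),
    hand_angle_raw = runif(n, -30, 30),
    rt_ms = round(rnorm(n, 440, 50) / 5) * 5,
    mt_ms = round(pmax(155, rnorm(n, 184, 20)) / 5) * 5)
  trajs <- simulate_trajectories(trials, traj_config(), seed = 22)
  for (i in seq_len(n)) {
    k <- process_trajectory(trajs[[i]], trials$target_deg[i])
    expect_true(k$complete)
    expect_lt(abs(k$hand_angle_deg - trials$hand_angle_raw[i]), 0.5)
    expect_lte(abs(k$rt_ms - trials$rt_ms[i]), 5 + 1e-9)
    expect_lte(abs(k$mt_ms - trials$mt_ms[i]), 5 + 1e-9)
  }
  # the canonical reach: programmed RT 440 ms detected within one sample
  one <- simulate_trajectories(data.frame(target_deg = 90,
                                          hand_angle_raw = 0,
                                          rt_ms = 440, mt_ms = 185),
                               traj_config(), seed = 3)
  ev <- detect_events(rotate_to_common_axis(filter_trajectory(one[[1]]), 90))
  expect_lte(abs(ev$rt_ms - 440), 5 + 1e-9)
  expect_lte(abs(ev$mt_ms - 185), 5 + 1e-9)
})

test_that("short-amplitude reaches are incomplete and flagged downstream", {
  tr <- simulate_trajectories(
    data.frame(target_deg = 90, hand_angle_raw = 0, amplitude_cm = 4),
    traj_config(), seed = 1)
  k <- process_trajectory(tr[[1]], 90)
  expect_false(k$complete)
  expect_lt(k$amplitude_cm, 5)
  ex <- apply_exclusions(data.frame(hand_angle_deg = c(rep(2, 30), k$hand_angle_deg),
                                    rt_ms = c(rnorm(30, 440, 20), k$rt_ms),
                                    mt_ms = c(rnorm(30, 184, 10), k$mt_ms),
                                    amplitude_cm = c(rep(6, 30), k$amplitude_cm)))
  expect_true(ex$excl_amplitude[31])
})

test_that("infeasible movement times are rejected", {
  expect_error(simulate_trajectories(
    data.frame(target_deg = 90, hand_angle_raw = 0, mt_ms = 10),
    traj_config(), seed = 1), "fewer than 3 samples")
})

test_that("trial tables serialize the full per-trial layout", {
  gs <- group_spec(n_participants = 2, noise_sd_deg = 3.5)
  co <- simulate_cohort(gs, group = "DT", seed = 6)
  rsvp <- lapply(1:2, function(i) simulate_rsvp(co$schedules[[i]],
                                                rsvp_spec(), seed = i))
  path <- tempfile(fileext = ".csv")
  tab <- write_trial_table(co, path, rsvp = rsvp)
  expect_true(file.exists(path))
  back <- read.csv(path)
  expect_equal(nrow(back), 2 * 284)
  expect_true(all(c("participant_id", "group", "trial", "cycle", "target_deg",
                    "feedback", "clamp_sign", "post_break", "hand_angle_deg",
                    "rsvp_correct", "rsvp_epoch") %in% names(back)))
  unlink(path)
})
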