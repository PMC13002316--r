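#' Configuration for the parameter-recovery experiment
#'
#' Tests whether a negative correlation between retention and error
#' sensitivity could be a fitting artifact: A and b are sampled
#' independently (so the generating correlation is 0 by construction),
#' trajectories are simulated with realistic noise, refit, and the
#' correlation of the recovered estimates is examined across replicate
#' experiments.
#'
#' @param n_trajectories total simulated trajectories (default 1000).
#' @param cohort_size trajectories per replicate experiment (default 24,
#'   one cohort's worth); the number of replicates is
#'   `n_replicates %||% floor(n_trajectories / cohort_size)`.
#' @param n_replicates optional explicit replicate count (overrides
#'   `n_trajectories`).
#' @param A_source,b_source marginal sources for the independent draws:
#'   either a numeric vector of samples (resampled with replacement, e.g.
#'   posterior draws) or `c(mean, sd)` of a normal truncated to the fitting
#'   bounds. Defaults use the dual-task group location with the
#'   participant-level dispersions of [group_spec()], so the generating
#'   spread reflects genuine individual differences.
#' @param noise_source residual noise: a single sigma (degrees, Gaussian
#'   per cycle; default 1.75, the cycle-level counterpart of the
#'   generator's 3.5-degree per-trial noise), or a numeric vector of
#'   residuals (e.g. pooled fit residuals) resampled with replacement.
#' @param max_fail_frac abort when more than this fraction of fits fail.
#' @param seed integer seed.
#' @return object of class `recovery_config`.
#' @export
recovery_config <- function(n_trajectories = 1000, cohort_size = 24,
                            n_replicates = NULL,
                            A_source = c(0.897, 0.05),
                            b_source = c(0.026, 0.012),
                            noise_source = 1.75, max_fail_frac = 0.2,
                            seed = 1L) {
  reps <- n_replicates %||% max(1L, floor(n_trajectories / cohort_size))
  structure(list(n_replicates = as.integer(reps),
                 cohort_size = as.integer(cohort_size),
                 A_source = A_source, b_source = b_source,
                 noise_source = noise_source,
                 max_fail_frac = max_fail_frac, seed = seed),
            class = "recovery_config")
}

# draw k values from a marginal source, truncated to [lo, hi]
draw_marginal <- function(source, k, lo, hi) {
  if (length(source) > 2) {
    src <- source[source >= lo & source <= hi]
    sample(src, k, replace = TRUE)
  } else {
    out <- numeric(0)
    while (length(out) < k) {
      cand <- stats::rnorm(2 * k, source[1], source[2])
      out <- c(out, cand[cand >= lo & cand <= hi])
    }
    out[seq_len(k)]
  }
}

#' Run the parameter-recovery experiment
#'
#' For each replicate: sample `cohort_size` (A, b) pairs independently,
#' simulate each participant's cycle-level trajectory with measurement
#' noise, refit the state-space model, and compute the Pearson correlation
#' of the recovered point estimates. The distribution of recovered
#' correlations across replicates is summarised by its median and 89%
#' highest density interval; `p_le` is the proportion of recovered
#' correlations at least as extreme (as low) as the observed correlation.
#'
#' @param config a [recovery_config()].
#' @param schedule a trial-level `clamp_schedule` (cycle-level simulation
#'   uses [schedule_cycles()] of it).
#' @param clamp_deg clamp magnitude in degrees.
#' @param fitcfg a [fit_config()]; fewer starts than the publication
#'   default are adequate here because the noiseless-window objective is
#'   smooth (see the methods vignette).
#' @param observed_r observed correlation the recovered distribution is
#'   compared against (default -0.68).
#' @return object of class `recovery_result`: `simulated_r`,
#'   `recovered_r` (per-replicate vector), `median_r`, `hdi` (89%),
#'   `observed_r`, `p_le`, `n_failed`.
#' @export
run_recovery <- function(config = recovery_config(), schedule = NULL,
                         clamp_deg = 45,
                         fitcfg = fit_config(n_starts = 10),
                         observed_r = -0.68) {
  stopifnot(inherits(config, "recovery_config"))
  if (is.null(schedule)) schedule <- make_schedule(seed = config$seed)
  cyc_sch <- schedule_cycles(schedule)
  bd <- ss_bounds()
  reps <- config$n_replicates
  csz <- config$cohort_size

  gen_A <- numeric(0)
  gen_b <- numeric(0)
  recovered <- rep(NA_real_, reps)
  n_failed <- 0L
  n_total <- 0L

  for (r in seq_len(reps)) {
    pars <- with_seed(derive_seed(config$seed, paste0("draw", r)), {
      cbind(A = draw_marginal(config$A_source, csz, bd$A[1], bd$A[2]),
            b = draw_marginal(config$b_source, csz, bd$b[1], bd$b[2]))
    })
    gen_A <- c(gen_A, pars[, "A"])
    gen_b <- c(gen_b, pars[, "b"])
    A_hat <- rep(NA_real_, csz)
    b_hat <- rep(NA_real_, csz)
    for (i in seq_len(csz)) {
      n_total <- n_total + 1L
      si <- derive_seed(config$seed, paste0("noise", r, "_", i))
      sim <- simulate_state_space(
        model_params(pars[i, "A"], pars[i, "b"], 1, level = "cycle"),
        cyc_sch, clamp_deg = clamp_deg, noise_sd = 0)
      noise <- with_seed(si, {
        if (length(config$noise_source) > 1) {
          sample(config$noise_source, nrow(cyc_sch), replace = TRUE)
        } else {
          stats::rnorm(nrow(cyc_sch), 0, config$noise_source)
        }
      })
      series <- data.frame(cycle = sim$cycle,
                           hand_angle = sim$hand_angle + noise)
      fit <- tryCatch(
        fit_state_space(series, cyc_sch, clamp_deg = clamp_deg,
                        config = fitcfg),
        error = function(e) NULL)
      if (is.null(fit)) {
        n_failed <- n_failed + 1L
      } else {
        A_hat[i] <- fit$params$A
        b_hat[i] <- fit$params$b
      }
    }
    ok <- !is.na(A_hat)
    if (sum(ok) >= 3) recovered[r] <- stats::cor(A_hat[ok], b_hat[ok])
    if (n_failed / n_total > config$max_fail_frac && n_total > 20) {
      stop(sprintf("recovery aborted: %d/%d fits failed", n_failed, n_total))
    }
  }

  recovered <- recovered[!is.na(recovered)]
  hd <- hdi(recovered, mass = 0.89)
  structure(list(
    simulated_r = stats::cor(gen_A, gen_b),
    recovered_r = recovered,
    median_r = stats::median(recovered),
    hdi = hd,
    observed_r = observed_r,
    p_le = mean(recovered <= observed_r),
    n_failed = n_failed
  ), class = "recovery_result")
}

#' @export
print.recovery_result <- function(x, ...) {
  cat(sprintf(
    "parameter recovery: simulated r = %.3f; recovered r median = %.3f, 89%% interval [%.3f, %.3f]\nPr(recovered <= observed %.2f) = %.3f over %d replicates (%d fit failures)\n",
    x$simulated_r, x$median_r, x$hdi[1], x$hdi[2], x$observed_r, x$p_le,
    length(x$recovered_r), x$n_failed))
  invisible(x)
}

#' MSE surface over a retention / error-sensitivity grid
#'
#' Diagnostic for the A-b degeneracy: different parameter combinations can
#' produce similar steady-state learning (equal b c / (1 - A)), so the
#' low-MSE valley around a reference trajectory runs along a negative
#' (A, b) slope.
#'
#' @param A_grid,b_grid grid values (within bounds).
#' @param reference an [model_params()] generating the reference
#'   trajectory.
#' @param schedule cycle-level schedule.
#' @param clamp_deg clamp magnitude.
#' @param fit_window cycle range of the comparison.
#' @return matrix of MSEs (rows = `A_grid`, cols = `b_grid`) with the
#'   grids as dimnames.
#' @export
degeneracy_map <- function(A_grid, b_grid, reference, schedule,
                           clamp_deg = 45, fit_window = 11:51) {
  stopifnot(inherits(reference, "ss_params"))
  win <- build_window(schedule, fit_window)
  ref <- predict_window(reference$A, reference$b, reference$d, win, clamp_deg)
  out <- matrix(NA_real_, length(A_grid), length(b_grid),
                dimnames = list(format(A_grid), format(b_grid)))
  for (i in seq_along(A_grid)) {
    for (j in seq_along(b_grid)) {
      pred <- predict_window(A_grid[i], b_grid[j], reference$d, win, clamp_deg)
      out[i, j] <- mean((ref - pred)^2)
    }
  }
  out
}
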