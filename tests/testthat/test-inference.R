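test_that("hdi returns the shortest mass interval", {
  set.seed(1)
  z <- rnorm(1e5)
  h <- hdi(z, 0.89)
  expect_equal(unname(h[1]), -1.598, tolerance = 0.02)
  expect_equal(unname(h[2]), 1.598, tolerance = 0.02)
  # constant samples collapse to a point
  expect_equal(unname(hdi(rep(3.3, 500))), c(3.3, 3.3))
  # flat density: width equals the mass
  u <- runif(1e5)
  hu <- hdi(u, 0.89)
  expect_equal(unname(hu[2] - hu[1]), 0.89, tolerance = 0.01)
  # skewed density: HDI is shorter than the central interval
  g <- rgamma(1e5, 2)
  hg <- hdi(g, 0.89)
  ci <- quantile(g, c(0.055, 0.945))
  expect_lt(hg[2] - hg[1], ci[2] - ci[1])
})

test_that("posterior summaries order their fields coherently", {
  set.seed(2)
  ps <- posterior_summary(rnorm(5000, 2, 1))
  expect_lte(ps$hdi_low, ps$median)
  expect_gte(ps$hdi_high, ps$median)
  expect_equal(ps$pr_direction, mean(ps$samples > 0))
})

test_that("robust group estimation recovers a known mean", {
  set.seed(3)
  y <- rnorm(24, 5, 2)
  f <- estimate_group_mean(y, sampler = quick_sampler(3))
  se <- 2 / sqrt(24)
  expect_lt(abs(f$mean$median - 5), 2 * se)
  expect_true(f$diagnostics$ok)
  expect_gt(f$diagnostics$ess, 400)
  # near-constant data: mean pinned at the constant
  y0 <- rep(3, 24) + rnorm(24, 0, 1e-3)
  f0 <- estimate_group_mean(y0, sampler = tiny_sampler(4))
  expect_equal(f0$mean$median, 3, tolerance = 0.01)
})

test_that("the scale-mixture sampler agrees with an independent JAGS fit", {
  set.seed(5)
  y <- c(rnorm(22, 8, 3), 25, -10)  # heavy-tailed sample
  own <- estimate_group_mean(y, sampler = quick_sampler(5))
  model <- "
  model {
    for (i in 1:N) { y[i] ~ dt(mu, 1 / (sig * sig), nu) }
    mu ~ dnorm(ybar, 1 / (30 * 30))
    prec ~ dgamma(2, b0)
    sig <- sqrt(1 / prec)
    nu <- 1 + ex
    ex ~ dexp(1 / 29)
  }"
  m <- rjags::jags.model(textConnection(model),
                         data = list(y = y, N = length(y), ybar = mean(y),
                                     b0 = var(y)),
                         n.chains = 2, quiet = TRUE)
  update(m, 1000, progress.bar = "none")
  s <- rjags::coda.samples(m, c("mu", "sig"), 4000, progress.bar = "none")
  ref <- as.matrix(do.call(rbind, lapply(s, as.matrix)))
  # same likelihood, near-identical priors (inverse-gamma on the variance):
  # posteriors agree to Monte-Carlo precision
  expect_equal(own$mean$median, median(ref[, "mu"]), tolerance = 0.05)
  expect_equal(own$sd$median, median(ref[, "sig"]), tolerance = 0.1)
})

test_that("group comparisons separate what is separated and not what is not", {
  set.seed(7)
  a <- rnorm(24, 5, 2)
  b <- a  # identical groups
  cg0 <- compare_groups(a, b, sampler = tiny_sampler(7))
  expect_equal(cg0$pr_direction, 0.5, tolerance = 0.1)
  expect_lte(cg0$effect$hdi_low, 0)
  expect_gte(cg0$effect$hdi_high, 0)
  # groups ten pooled-sd apart
  cg1 <- compare_groups(rnorm(24, 20, 1), rnorm(24, 0, 1),
                        sampler = tiny_sampler(8))
  expect_gt(cg1$pr_direction, 0.999)
  expect_gt(cg1$effect$median, 5)
})

test_that("windowed contrasts recover the generating direction", {
  gs_lo <- group_spec(mean_A = 0.917, mean_b = 0.020, sd_A = 0.02,
                      sd_b = 0.004, n_participants = 12)
  gs_hi <- group_spec(mean_A = 0.893, mean_b = 0.033, sd_A = 0.02,
                      sd_b = 0.004, n_participants = 12)
  lo <- simulate_cohort(gs_lo, "ST", level = "cycle", seed = 21)
  hi <- simulate_cohort(gs_hi, "DTF", level = "cycle", seed = 22)
  wc <- windowed_contrast(hi$cycles, lo$cycles, window = 13:17,
                          sampler = tiny_sampler(9))
  expect_gt(wc$difference$median, 0)
  # same cohorts, identical windows: difference straddles zero
  wc0 <- windowed_contrast(lo$cycles, lo$cycles, window = 13:17,
                           sampler = tiny_sampler(10))
  expect_lte(wc0$difference$hdi_low, 0)
  expect_gte(wc0$difference$hdi_high, 0)
})

test_that("hierarchical binomial model recovers epoch accuracies", {
  sch <- default_schedule()
  recs <- do.call(rbind, lapply(1:24, function(j) {
    r <- simulate_rsvp(sch, rsvp_spec(), seed = 300 + j)
    r$participant <- j
    r
  }))
  # short exploratory chains: R-hat alerts are expected and not at issue here
  af <- suppressWarnings(fit_accuracy_model(recs, sampler = quick_sampler(11)))
  gen <- c(baseline = 0.72, onset = 0.53, early = 0.66, late = 0.66)
  for (e in names(gen)) {
    # the posterior concentrates on the dataset's empirical rate ...
    emp <- mean(recs$correct[recs$epoch == e])
    expect_lte(af$accuracy[[e]]$hdi_low, emp)
    expect_gte(af$accuracy[[e]]$hdi_high, emp)
    # ... which sits within binomial sampling error of the generator
    n_e <- sum(recs$epoch == e)
    expect_lt(abs(af$accuracy[[e]]$median - gen[[e]]),
              3.2 * sqrt(gen[[e]] * (1 - gen[[e]]) / n_e) + 0.01)
  }
  # onset odds ratio clearly below 1, its HDI excluding 1
  expect_lt(af$odds_ratio$onset$hdi_high, 1)
})

test_that("flat generator accuracies give odds ratios covering 1", {
  sch <- default_schedule()
  flat <- rsvp_spec(c(baseline = 0.7, onset = 0.7, early = 0.7, late = 0.7,
                      other = 0.7))
  recs <- do.call(rbind, lapply(1:16, function(j) {
    r <- simulate_rsvp(sch, flat, seed = 500 + j)
    r$participant <- j
    r
  }))
  af <- fit_accuracy_model(recs, sampler = tiny_sampler(12))
  emp_base <- mean(recs$correct[recs$epoch == "baseline"])
  for (e in names(af$odds_ratio)) {
    # interval covers the dataset's empirical odds ratio and the point
    # estimate stays near 1 (no systematic epoch effect)
    emp_e <- mean(recs$correct[recs$epoch == e])
    emp_or <- (emp_e / (1 - emp_e)) / (emp_base / (1 - emp_base))
    expect_lte(af$odds_ratio[[e]]$hdi_low, emp_or)
    expect_gte(af$odds_ratio[[e]]$hdi_high, emp_or)
    expect_gt(af$odds_ratio[[e]]$median, 0.7)
    expect_lt(af$odds_ratio[[e]]$median, 1.4)
  }
})

test_that("bayesian correlation tracks strong, absent and negative dependence", {
  set.seed(13)
  x <- rnorm(24)
  # near-degenerate correlations mix slowly at these short test chains;
  # the R-hat alert is expected
  near <- suppressWarnings(bayes_correlation(x, x + rnorm(24, 0, 0.05),
                                             sampler = tiny_sampler(13)))
  expect_gt(near$median, 0.9)
  neg <- suppressWarnings(bayes_correlation(x, -x + rnorm(24, 0, 0.2),
                                            sampler = tiny_sampler(14)))
  expect_lt(neg$median, -0.9)
  ind <- bayes_correlation(x, rnorm(24), sampler = tiny_sampler(15))
  expect_lte(ind$hdi_low, 0)
  expect_gte(ind$hdi_high, 0)
  expect_lt(ind$hdi_high - ind$hdi_low, 1.1)
  expect_error(bayes_correlation(x, rep(1, 24)), "zero-variance")
  expect_error(bayes_correlation(x[1:3], x[1:3]), "at least 5")
})

test_that("joint (A, b) model recovers means and correlation", {
  gs <- group_spec(mean_A = 0.9, mean_b = 0.025, corr_Ab = -0.6,
                   sd_A = 0.04, sd_b = 0.007, n_participants = 24)
  pp <- draw_participants(gs, seed = 17)
  jf <- fit_joint_ab(pp, sampler = quick_sampler(17))
  expect_lte(jf$corr$hdi_low, -0.6)
  expect_gte(jf$corr$hdi_high, -0.6)
  expect_lt(jf$corr$median, -0.2)
  expect_lt(abs(jf$mean_A$median - 0.9), 0.03)
  expect_lt(abs(jf$mean_b$median - 0.025), 0.005)
  # zero-correlation generator: HDI covers 0
  gs0 <- group_spec(mean_A = 0.9, mean_b = 0.025, corr_Ab = 0,
                    sd_A = 0.04, sd_b = 0.007, n_participants = 24)
  jf0 <- fit_joint_ab(draw_participants(gs0, seed = 18),
                      sampler = tiny_sampler(18))
  expect_lte(jf0$corr$hdi_low, 0)
  expect_gte(jf0$corr$hdi_high, 0)
})

test_that("ordered generating error sensitivities yield a favoured ordering", {
  mk <- function(b, seed) {
    draw_participants(group_spec(mean_A = 0.9, mean_b = b, sd_A = 0.03,
                                 sd_b = 0.005, n_participants = 24),
                      seed = seed)
  }
  fits <- list(fit_joint_ab(mk(0.020, 21), sampler = tiny_sampler(21)),
               fit_joint_ab(mk(0.026, 22), sampler = tiny_sampler(22)),
               fit_joint_ab(mk(0.033, 23), sampler = tiny_sampler(23)))
  expect_gt(ordering_probability(fits, "mean_b"), 0.5)
})

test_that("posterior predictive bands collapse for a degenerate posterior", {
  cyc <- default_cycles()
  delta <- cbind(mean_A = rep(0.917, 200), mean_b = rep(0.020, 200))
  pp <- posterior_predictive_trajectories(delta, cyc, n_draws = 100)
  expect_equal(pp$lower, pp$upper, tolerance = 1e-12)
  ref <- simulate_state_space(model_params(0.917, 0.020), cyc)$hand_angle
  expect_equal(pp$median, ref, tolerance = 1e-12)
  # difference from itself is identically zero
  pp0 <- posterior_predictive_trajectories(delta, cyc, reference = delta,
                                           n_draws = 100)
  expect_true(all(abs(pp0$diff_median) < 1e-12))
})

test_that("type S and M behave at the extremes", {
  set.seed(25)
  well <- type_sm(rnorm(5000, 5, 0.1), n_per_group = 24, noise_sd = 0.5,
                  n_sims = 4000, seed = 1)
  expect_lt(well$type_s, 0.01)
  expect_equal(well$type_m, 1, tolerance = 0.05)
  centred <- type_sm(rnorm(5000, 0, 1), n_per_group = 24, noise_sd = 1,
                     n_sims = 4000, seed = 2)
  expect_equal(centred$type_s, 0.5, tolerance = 0.05)
  # a posterior with ~95% directional certainty: sign errors of order 0.1
  unc <- type_sm(rnorm(5000, 1.5, 1), n_per_group = 24, noise_sd = 5,
                 n_sims = 4000, seed = 3)
  expect_gt(unc$type_s, 0.02)
  expect_lt(unc$type_s, 0.35)
  expect_gt(unc$type_m, 1)
})

test_that("concordance matches its closed form and reduces to Pearson", {
  expect_equal(concordance(1:10, 1:10), 1)
  expect_equal(concordance(c(1, 2, 3), c(2, 3, 4)), 4 / 7)
  x <- c(-2, -1, 0, 1, 2)
  expect_equal(concordance(x, -x), -1)
  # equal means and variances: rho_c equals Pearson r
  set.seed(27)
  a <- rnorm(200)
  b <- 0.6 * a + sqrt(1 - 0.36) * rnorm(200)
  a <- (a - mean(a)) / sd(a)
  b <- (b - mean(b)) / sd(b)
  expect_equal(concordance(a, b), cor(a, b), tolerance = 1e-12)
  # Bayesian wrapper concentrates near the point value
  cb <- concordance(a, b, bayes = TRUE, n_draws = 2000, seed = 5)
  expect_equal(cb$median, cor(a, b), tolerance = 0.05)
})

test_that("hdi coverage is calibrated near its nominal mass", {
  # moderate-n check kept quick; the full 1,000-dataset calibration runs in
  # the acceptance suite
  set.seed(29)
  cover <- vapply(seq_len(200), function(i) {
    y <- rnorm(24, 5, 2)
    f <- suppressWarnings(
      estimate_group_mean(y, sampler = sampler_config(chains = 2,
                                                      iterations = 800,
                                                      warmup = 150,
                                                      seed = i)))
    f$mean$hdi_low <= 5 && f$mean$hdi_high >= 5
  }, logical(1))
  expect_equal(mean(cover), 0.89, tolerance = 0.075)
})
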