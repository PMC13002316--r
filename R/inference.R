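#' Sampler configuration
#'
#' Defaults follow the conventional settings for this analysis family:
#' 4 chains of 3,500 iterations each with 1,000 warm-up per chain.
#' `adapt_delta` and `max_treedepth` are Hamiltonian-sampler tuning fields
#' kept for configuration compatibility; the Gibbs-based samplers in this
#' package do not use them.
#'
#' @param chains number of chains.
#' @param iterations total iterations per chain (including warmup).
#' @param warmup warm-up iterations per chain.
#' @param adapt_delta,max_treedepth HMC tuning fields (unused here).
#' @param seed integer seed.
#' @return object of class `sampler_config`.
#' @export
sampler_config <- function(chains = 4, iterations = 3500, warmup = 1000,
                           adapt_delta = 0.9, max_treedepth = 10,
                           seed = 1L) {
  stopifnot(chains >= 1, iterations > warmup, warmup >= 0)
  structure(list(chains = as.integer(chains),
                 iterations = as.integer(iterations),
                 warmup = as.integer(warmup),
                 adapt_delta = adapt_delta,
                 max_treedepth = max_treedepth, seed = seed),
            class = "sampler_config")
}

#' Highest density interval
#'
#' Shortest contiguous interval containing the requested probability mass
#' of the samples (default 89%).
#'
#' @param samples numeric vector of draws.
#' @param mass probability mass in (0, 1).
#' @return named numeric vector `c(lower, upper)`.
#' @examples
#' hdi(rnorm(1e5), 0.89)  # about c(-1.6, 1.6)
#' @export
hdi <- function(samples, mass = 0.89) {
  stopifnot(mass > 0, mass < 1)
  s <- sort(samples[is.finite(samples)])
  n <- length(s)
  if (n < 2) return(c(lower = s[1], upper = s[1]))
  k <- max(1L, ceiling(mass * n))
  if (k >= n) return(c(lower = s[1], upper = s[n]))
  widths <- s[(k + 1):n] - s[1:(n - k)]
  i <- which.min(widths)
  c(lower = s[i], upper = s[i + k])
}

#' Summarise a posterior sample
#'
#' @param samples numeric draws.
#' @param mass HDI mass (default 0.89).
#' @param threshold direction threshold: `pr_direction` is the posterior
#'   probability that the quantity exceeds it (default 0).
#' @return object of class `posterior_summary`: `median`, `hdi_low`,
#'   `hdi_high`, `pr_direction`, `mass`, `samples`.
#' @export
posterior_summary <- function(samples, mass = 0.89, threshold = 0) {
  hd <- hdi(samples, mass)
  structure(list(median = stats::median(samples),
                 hdi_low = unname(hd[1]), hdi_high = unname(hd[2]),
                 pr_direction = mean(samples > threshold),
                 mass = mass, samples = samples),
            class = "posterior_summary")
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat(sprintf("median %.3f, %d%% HDI [%.3f, %.3f], Pr(>thr) = %.3f (n = %d draws)\n",
              x$median, round(100 * x$mass), x$hdi_low, x$hdi_high,
              x$pr_direction, length(x$samples)))
  invisible(x)
}

# split-half R-hat over a draws matrix (iterations x chains)
split_rhat <- function(draws) {
  half <- floor(nrow(draws) / 2)
  sub <- cbind(draws[1:half, , drop = FALSE],
               draws[(half + 1):(2 * half), , drop = FALSE])
  m <- ncol(sub)
  n <- nrow(sub)
  means <- colMeans(sub)
  vars <- apply(sub, 2, stats::var)
  B <- n * stats::var(means)
  W <- mean(vars)
  if (W < 1e-300) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# MH-within-Gibbs sampler for the robust (Student-t) group model
# y_i ~ t_nu(mu, sigma); scale-mixture latent lambda_i ~ Gamma(nu/2, nu/2)
best_gibbs_chain <- function(y, prior, n_iter, n_warmup) {
  n <- length(y)
  mu0 <- prior$mu_loc
  tau0 <- 1 / prior$mu_sd^2
  a0 <- prior$sigma_shape
  b0 <- prior$sigma_rate
  nu_rate <- 1 / prior$nu_mean_excess

  mu <- mean(y)
  sigma2 <- max(stats::var(y), 1e-6)
  nu <- 10
  lam <- rep(1, n)

  keep <- n_iter - n_warmup
  out <- matrix(NA_real_, keep, 3, dimnames = list(NULL, c("mu", "sigma", "nu")))
  log_nu_post <- function(nu, lam) {
    n * (nu / 2 * log(nu / 2) - lgamma(nu / 2)) +
      (nu / 2 - 1) * sum(log(lam)) - nu / 2 * sum(lam) -
      nu_rate * (nu - 1)
  }
  for (it in seq_len(n_iter)) {
    z2 <- (y - mu)^2 / sigma2
    lam <- stats::rgamma(n, (nu + 1) / 2, rate = (nu + z2) / 2)
    prec <- tau0 + sum(lam) / sigma2
    mhat <- (tau0 * mu0 + sum(lam * y) / sigma2) / prec
    mu <- stats::rnorm(1, mhat, sqrt(1 / prec))
    sigma2 <- 1 / stats::rgamma(1, a0 + n / 2,
                                rate = b0 + 0.5 * sum(lam * (y - mu)^2))
    # random-walk MH on log(nu - 1); a small and a large proposal per sweep
    # keep the heavy upper tail of nu well mixed
    for (sc in c(0.3, 1.2)) {
      prop <- 1 + (nu - 1) * exp(stats::rnorm(1, 0, sc))
      logr <- log_nu_post(prop, lam) - log_nu_post(nu, lam) +
        log(prop - 1) - log(nu - 1)
      if (is.finite(logr) && log(stats::runif(1)) < logr) nu <- prop
    }
    if (it > n_warmup) out[it - n_warmup, ] <- c(mu, sqrt(sigma2), nu)
  }
  out
}

#' Robust Bayesian estimation of a group mean
#'
#' Student-t likelihood y_i ~ t_nu(mu, sigma) with a normal prior on the
#' mean centred on the sample mean (dispersion 30 degrees by default, the
#' wide hand-angle prior), an inverse-gamma prior on the variance
#' moment-matched to the sample variance, and a shifted-exponential prior
#' on the normality parameter nu (mean 30). Sampled by an exact
#' scale-mixture Gibbs sampler with a Metropolis step for nu; convergence
#' is checked with split R-hat and effective sample size.
#'
#' @param values per-participant scalars (n >= 3).
#' @param prior optional overrides: `mu_loc`, `mu_sd`, `sigma_shape`,
#'   `sigma_rate`, `nu_mean_excess`.
#' @param sampler a [sampler_config()].
#' @return list of class `group_mean_fit`: `mean`, `sd`, `nu`
#'   (posterior_summary objects), `draws` (matrix), `diagnostics`
#'   (`rhat`, `ess`, `ok`).
#' @export
estimate_group_mean <- function(values, prior = list(),
                                sampler = sampler_config()) {
  stopifnot(length(values) >= 3, all(is.finite(values)))
  pr <- utils::modifyList(list(
    mu_loc = mean(values), mu_sd = 30,
    sigma_shape = 2, sigma_rate = max(stats::var(values), 1e-6),
    nu_mean_excess = 29
  ), prior)

  chains <- with_seed(sampler$seed, {
    lapply(seq_len(sampler$chains), function(ch) {
      best_gibbs_chain(values, pr, sampler$iterations, sampler$warmup)
    })
  })
  draws <- do.call(rbind, chains)
  mu_mat <- sapply(chains, function(m) m[, "mu"])
  rhat <- split_rhat(mu_mat)
  ess <- tryCatch(as.numeric(coda::effectiveSize(coda::mcmc(draws[, "mu"]))),
                  error = function(e) NA_real_)
  diag_ok <- is.finite(rhat) && rhat < 1.01
  if (!diag_ok) warning(sprintf("group-mean sampler: split R-hat %.3f >= 1.01", rhat))

  structure(list(
    mean = posterior_summary(draws[, "mu"]),
    sd = posterior_summary(draws[, "sigma"]),
    nu = posterior_summary(draws[, "nu"]),
    draws = draws,
    diagnostics = list(rhat = rhat, ess = ess, ok = diag_ok)
  ), class = "group_mean_fit")
}

#' Bayesian comparison of two independent groups
#'
#' Robust group-mean estimation per group, then draw-wise difference of
#' means and a standardized effect size: the mean difference divided by
#' the square root of the average of the two groups' posterior variances.
#'
#' @param a,b per-participant scalars for the two groups.
#' @param prior,sampler as in [estimate_group_mean()].
#' @return list of class `group_comparison`: `difference` and `effect`
#'   (posterior_summary), `pr_direction` (P(a > b)), `fit_a`, `fit_b`.
#' @export
compare_groups <- function(a, b, prior = list(), sampler = sampler_config()) {
  fa <- estimate_group_mean(a, prior, sampler)
  sb <- sampler
  sb$seed <- derive_seed(sampler$seed, "group_b")
  fb <- estimate_group_mean(b, prior, sb)
  k <- min(nrow(fa$draws), nrow(fb$draws))
  diff <- fa$draws[1:k, "mu"] - fb$draws[1:k, "mu"]
  pooled <- sqrt((fa$draws[1:k, "sigma"]^2 + fb$draws[1:k, "sigma"]^2) / 2)
  structure(list(
    difference = posterior_summary(diff),
    effect = posterior_summary(diff / pooled),
    pr_direction = mean(diff > 0),
    fit_a = fa, fit_b = fb
  ), class = "group_comparison")
}

# run a JAGS model with per-chain seeded RNG; returns combined draws matrix
run_jags <- function(model_string, data, params, sampler,
                     inits_extra = NULL) {
  inits <- lapply(seq_len(sampler$chains), function(ch) {
    c(list(.RNG.name = "base::Mersenne-Twister",
           .RNG.seed = derive_seed(sampler$seed, paste0("chain", ch))),
      inits_extra)
  })
  m <- rjags::jags.model(textConnection(model_string), data = data,
                         inits = inits, n.chains = sampler$chains,
                         quiet = TRUE)
  stats::update(m, sampler$warmup, progress.bar = "none")
  s <- rjags::coda.samples(m, params, sampler$iterations - sampler$warmup,
                           progress.bar = "none")
  gd <- tryCatch(coda::gelman.diag(s, autoburnin = FALSE,
                                   multivariate = FALSE)$psrf[, 1],
                 error = function(e) NA_real_)
  if (any(is.finite(gd) & gd >= 1.01)) {
    warning("JAGS sampler: split R-hat >= 1.01 for some parameters")
  }
  list(draws = as.matrix(do.call(rbind, lapply(s, as.matrix))),
       rhat = gd,
       ess = tryCatch(coda::effectiveSize(s), error = function(e) NA))
}

#' Hierarchical binomial model of report accuracy
#'
#' Logit-scale model with participant random intercepts and fixed epoch
#' effects (baseline as reference): logit(p) = alpha_j + beta_epoch.
#' Priors: epoch effects N(0, 1.5); participant-intercept mean N(0, 1.5);
#' intercept SD uniform(0, 3). Returns posterior epoch accuracies for the
#' population-typical participant and odds ratios relative to baseline.
#'
#' @param records data.frame with columns `participant`, `epoch`,
#'   `correct` (0/1); epochs other than `baseline`, `onset`, `early`,
#'   `late` are dropped.
#' @param sampler a [sampler_config()].
#' @return list of class `accuracy_fit`: `accuracy` (named list of
#'   posterior_summary per epoch), `odds_ratio` (vs baseline),
#'   `diagnostics`.
#' @export
fit_accuracy_model <- function(records, sampler = sampler_config()) {
  stopifnot(all(c("participant", "epoch", "correct") %in% names(records)))
  epochs <- c("baseline", "onset", "early", "late")
  rec <- records[records$epoch %in% epochs, ]
  agg <- stats::aggregate(correct ~ participant + epoch, data = rec,
                          FUN = function(v) c(k = sum(v), n = length(v)))
  k <- agg$correct[, "k"]
  ntr <- agg$correct[, "n"]
  pid <- as.integer(factor(agg$participant))
  eid <- match(agg$epoch, epochs)
  if (min(table(unique(cbind(pid, eid))[, 1])) < 2) {
    stop("every participant needs trials in at least 2 epochs")
  }

  model <- "
  model {
    for (i in 1:N) {
      k[i] ~ dbin(p[i], n[i])
      logit(p[i]) <- alpha[pid[i]] + beta[eid[i]]
    }
    beta[1] <- 0
    for (e in 2:E) { beta[e] ~ dnorm(0, 1 / (1.5 * 1.5)) }
    for (j in 1:J) { alpha[j] ~ dnorm(mu_a, tau_a) }
    mu_a ~ dnorm(0, 1 / (1.5 * 1.5))
    sigma_a ~ dunif(0, 3)
    tau_a <- 1 / (sigma_a * sigma_a)
  }"
  res <- run_jags(model,
                  data = list(k = k, n = ntr, pid = pid, eid = eid,
                              N = length(k), J = max(pid), E = length(epochs)),
                  params = c("mu_a", "beta", "sigma_a"), sampler = sampler)
  d <- res$draws
  beta <- cbind(0, d[, paste0("beta[", 2:4, "]")])
  acc <- lapply(seq_along(epochs), function(e) {
    posterior_summary(inv_logit(d[, "mu_a"] + beta[, e]))
  })
  names(acc) <- epochs
  orat <- lapply(2:4, function(e) posterior_summary(exp(beta[, e]),
                                                    threshold = 1))
  names(orat) <- epochs[-1]
  structure(list(accuracy = acc, odds_ratio = orat,
                 diagnostics = list(rhat = res$rhat, ess = res$ess)),
            class = "accuracy_fit")
}

#' Bayesian correlation of paired scalars
#'
#' Bivariate normal model on standardized values with a uniform(-1, 1)
#' prior on the correlation.
#'
#' @param x,y paired vectors (n >= 5 complete pairs).
#' @param sampler a [sampler_config()].
#' @return `posterior_summary` of the correlation (with `diagnostics`
#'   attribute).
#' @export
bayes_correlation <- function(x, y, sampler = sampler_config()) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 5) stop("need at least 5 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero-variance input: correlation undefined")
  }
  zs <- cbind((x - mean(x)) / stats::sd(x), (y - mean(y)) / stats::sd(y))
  model <- "
  model {
    for (i in 1:N) { z[i, 1:2] ~ dmnorm(mu[1:2], Omega[1:2, 1:2]) }
    mu[1] ~ dnorm(0, 0.25)
    mu[2] ~ dnorm(0, 0.25)
    s1 ~ dunif(0.01, 10)
    s2 ~ dunif(0.01, 10)
    r ~ dunif(-0.999, 0.999)
    Sigma[1,1] <- s1 * s1
    Sigma[2,2] <- s2 * s2
    Sigma[1,2] <- r * s1 * s2
    Sigma[2,1] <- Sigma[1,2]
    Omega[1:2, 1:2] <- inverse(Sigma[1:2, 1:2])
  }"
  res <- run_jags(model, data = list(z = zs, N = nrow(zs)),
                  params = "r", sampler = sampler)
  out <- posterior_summary(as.numeric(res$draws[, "r"]))
  attr(out, "diagnostics") <- list(rhat = res$rhat, ess = res$ess)
  out
}

#' Joint group-level model of retention and error sensitivity
#'
#' Per-participant point estimates (A_i, b_i) are modelled on transformed
#' scales, (logit A_i, log b_i) ~ bivariate normal, with wide normal
#' priors on the means, uniform priors on the scales and a uniform(-1, 1)
#' prior on the correlation. Reported group means are the back-transformed
#' location parameters; the correlation is on the transformed scale.
#'
#' @param estimates data.frame with columns `A` and `b` (one group,
#'   n >= 10).
#' @param sampler a [sampler_config()].
#' @return list of class `joint_ab_fit`: `mean_A`, `mean_b`, `corr`
#'   (posterior_summary), `draws` (matrix with columns `mean_A`, `mean_b`,
#'   `corr`), `diagnostics`.
#' @export
fit_joint_ab <- function(estimates, sampler = sampler_config()) {
  stopifnot(all(c("A", "b") %in% names(estimates)), nrow(estimates) >= 10)
  z <- cbind(logit(pmin(pmax(estimates$A, 0.0101), 0.9989)),
             log(pmax(estimates$b, 0.00101)))
  model <- "
  model {
    for (i in 1:N) { z[i, 1:2] ~ dmnorm(mu[1:2], Omega[1:2, 1:2]) }
    mu[1] ~ dnorm(m1, 0.04)
    mu[2] ~ dnorm(m2, 0.04)
    s1 ~ dunif(0.01, 10)
    s2 ~ dunif(0.01, 10)
    r ~ dunif(-0.999, 0.999)
    Sigma[1,1] <- s1 * s1
    Sigma[2,2] <- s2 * s2
    Sigma[1,2] <- r * s1 * s2
    Sigma[2,1] <- Sigma[1,2]
    Omega[1:2, 1:2] <- inverse(Sigma[1:2, 1:2])
  }"
  res <- run_jags(model,
                  data = list(z = z, N = nrow(z),
                              m1 = mean(z[, 1]), m2 = mean(z[, 2])),
                  params = c("mu", "r"), sampler = sampler)
  d <- res$draws
  draws <- cbind(mean_A = inv_logit(d[, "mu[1]"]),
                 mean_b = exp(d[, "mu[2]"]),
                 corr = d[, "r"])
  structure(list(
    mean_A = posterior_summary(draws[, "mean_A"]),
    mean_b = posterior_summary(draws[, "mean_b"]),
    corr = posterior_summary(draws[, "corr"]),
    draws = draws,
    diagnostics = list(rhat = res$rhat, ess = res$ess)
  ), class = "joint_ab_fit")
}

#' Posterior probability of a monotonic group ordering
#'
#' Probability that a parameter increases strictly across groups in the
#' listed order, computed draw-wise from independent group posteriors.
#'
#' @param fits list of [fit_joint_ab()] results, in the hypothesised
#'   increasing order.
#' @param param column of the draws to compare (default `"mean_b"`).
#' @return scalar probability.
#' @export
ordering_probability <- function(fits, param = "mean_b") {
  k <- min(vapply(fits, function(f) nrow(f$draws), integer(1)))
  mat <- sapply(fits, function(f) f$draws[1:k, param])
  mean(apply(mat, 1, function(v) all(diff(v) > 0)))
}

#' Posterior predictive learning trajectories
#'
#' For each joint posterior draw of (A, b), simulates the noiseless
#' cycle-level trajectory over the schedule and summarises each cycle with
#' the posterior median and 89% HDI. With a reference fit, per-cycle
#' difference curves are computed draw-wise.
#'
#' @param fit a [fit_joint_ab()] result (or matrix/data.frame with columns
#'   `mean_A`, `mean_b`).
#' @param schedule cycle-level schedule.
#' @param clamp_deg clamp magnitude.
#' @param reference optional second fit for difference curves.
#' @param n_draws posterior draws to propagate (subsampled; default 1000).
#' @param mass interval mass.
#' @param seed integer seed for the subsampling.
#' @return data.frame per cycle: `cycle`, `median`, `lower`, `upper`, and
#'   (with a reference) `diff_median`, `diff_lower`, `diff_upper`.
#' @export
posterior_predictive_trajectories <- function(fit, schedule, clamp_deg = 45,
                                              reference = NULL,
                                              n_draws = 1000, mass = 0.89,
                                              seed = 1L) {
  draws <- if (inherits(fit, "joint_ab_fit")) fit$draws else as.matrix(fit)
  idx <- with_seed(seed, {
    if (nrow(draws) > n_draws) sample(nrow(draws), n_draws) else seq_len(nrow(draws))
  })
  sim_one <- function(A, b) {
    simulate_state_space(model_params(A, b, 1, level = "cycle"), schedule,
                         clamp_deg = clamp_deg)$hand_angle
  }
  mat <- vapply(idx, function(i) sim_one(draws[i, "mean_A"],
                                         draws[i, "mean_b"]),
                numeric(nrow(schedule)))
  out <- data.frame(
    cycle = schedule$cycle,
    median = apply(mat, 1, stats::median),
    lower = apply(mat, 1, function(v) hdi(v, mass)[1]),
    upper = apply(mat, 1, function(v) hdi(v, mass)[2])
  )
  if (!is.null(reference)) {
    rdraws <- if (inherits(reference, "joint_ab_fit")) reference$draws else as.matrix(reference)
    ridx <- with_seed(derive_seed(seed, "reference"), {
      if (nrow(rdraws) > length(idx)) sample(nrow(rdraws), length(idx)) else seq_len(nrow(rdraws))
    })
    rmat <- vapply(ridx, function(i) sim_one(rdraws[i, "mean_A"],
                                             rdraws[i, "mean_b"]),
                   numeric(nrow(schedule)))
    k <- min(ncol(mat), ncol(rmat))
    dmat <- mat[, 1:k, drop = FALSE] - rmat[, 1:k, drop = FALSE]
    out$diff_median <- apply(dmat, 1, stats::median)
    out$diff_lower <- apply(dmat, 1, function(v) hdi(v, mass)[1])
    out$diff_upper <- apply(dmat, 1, function(v) hdi(v, mass)[2])
  }
  out
}

#' Type S and Type M error rates, marginalised over the posterior
#'
#' For each simulation a true effect is drawn from the effect posterior, a
#' replicate two-group experiment is simulated (group size `n_per_group`,
#' Gaussian noise `noise_sd`), and its estimated effect is recorded.
#' Type S is the probability that the replicate estimate disagrees in sign
#' with the posterior median; Type M is the mean exaggeration ratio
#' |estimate| / |true effect|.
#'
#' @param effect_draws posterior draws of the effect (e.g. a group mean
#'   difference).
#' @param n_per_group replicate group size.
#' @param noise_sd replicate observation noise (posterior scale estimate).
#' @param n_sims number of simulations.
#' @param seed integer seed.
#' @return list with `type_s` and `type_m`.
#' @export
type_sm <- function(effect_draws, n_per_group, noise_sd, n_sims = 10000,
                    seed = 1L) {
  med <- stats::median(effect_draws)
  if (med == 0) stop("posterior median exactly 0: sign undefined")
  with_seed(seed, {
    true_eff <- sample(effect_draws, n_sims, replace = TRUE)
    se <- noise_sd * sqrt(2 / n_per_group)
    est <- stats::rnorm(n_sims, true_eff, se)
    list(type_s = mean(sign(est) != sign(med)),
         type_m = mean(abs(est) / pmax(abs(true_eff), 1e-12)))
  })
}

#' Concordance correlation coefficient
#'
#' Agreement between paired measurements, penalising both correlation
#' shortfall and location/scale shift:
#' rho_c = 2 cov(x, y) / (var(x) + var(y) + (mean(x) - mean(y))^2), with
#' population-moment (1/n) denominators. With `bayes = TRUE` the
#' coefficient is computed over Bayesian-bootstrap (Dirichlet-weighted)
#' draws of the moments.
#'
#' @param x,y paired vectors (n >= 3).
#' @param bayes return a posterior over rho_c instead of a point value.
#' @param n_draws Bayesian-bootstrap draws.
#' @param seed integer seed.
#' @return scalar rho_c, or a `posterior_summary` when `bayes = TRUE`.
#' @export
concordance <- function(x, y, bayes = FALSE, n_draws = 4000, seed = 1L) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  stopifnot(n >= 3)
  rho_c <- function(w) {
    w <- w / sum(w)
    mx <- sum(w * x); my <- sum(w * y)
    vx <- sum(w * (x - mx)^2); vy <- sum(w * (y - my)^2)
    cxy <- sum(w * (x - mx) * (y - my))
    if (vx + vy == 0) stop("both variances zero: concordance undefined")
    2 * cxy / (vx + vy + (mx - my)^2)
  }
  if (!bayes) return(rho_c(rep(1, n)))
  draws <- with_seed(seed, {
    vapply(seq_len(n_draws), function(i) {
      rho_c(stats::rgamma(n, 1))
    }, numeric(1))
  })
  posterior_summary(draws)
}

#' Group contrast of window-averaged hand angle
#'
#' Averages each participant's series over a cycle window, then compares
#' the two groups with [compare_groups()]; scanning adjacent windows
#' assesses sensitivity to window selection.
#'
#' @param series_a,series_b lists of per-participant cycle series
#'   (data.frames with `cycle`, `hand_angle`).
#' @param window cycle range (e.g. 13:17).
#' @param prior,sampler passed to [compare_groups()].
#' @return a `group_comparison` with attribute `window`.
#' @export
windowed_contrast <- function(series_a, series_b, window, prior = list(),
                              sampler = sampler_config()) {
  stopifnot(length(window) >= 1)
  wmean <- function(s) {
    v <- s$hand_angle[s$cycle %in% window]
    if (length(v) == 0) stop("empty window for some participant")
    mean(v, na.rm = TRUE)
  }
  out <- compare_groups(vapply(series_a, wmean, numeric(1)),
                        vapply(series_b, wmean, numeric(1)),
                        prior = prior, sampler = sampler)
  attr(out, "window") <- window
  out
}
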