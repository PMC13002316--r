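#' Parameter bounds for the single-rate state-space model
#'
#' Retention A in [0.01, 0.999], error sensitivity b in [0.001, 0.75],
#' set-break decay exponent d in [1, 2]. Used both to validate parameters
#' and to draw the uniform multi-start initialisations for fitting.
#'
#' @return named list of length-2 numeric ranges for `A`, `b`, `d`.
#' @export
ss_bounds <- function() {
  list(A = c(0.01, 0.999), b = c(0.001, 0.75), d = c(1, 2))
}

#' Construct state-space model parameters
#'
#' The single-rate model of trial-by-trial motor adaptation: the internal
#' state x (the learner's estimate of the visuomotor mapping) evolves as
#' \deqn{x_{n+1} = A x_n + b e_n,}
#' where A is retention (fraction of the state carried to the next step), b
#' is error sensitivity (update gain on the sensory prediction error e_n),
#' and across an extended pause (set break) retention becomes A^d for one
#' step, increasing forgetting. The motor output is y_n = -x_n + noise.
#'
#' @param A retention, in [0.01, 0.999].
#' @param b error sensitivity, in [0.001, 0.75].
#' @param d set-break decay exponent, in [1, 2].
#' @param level `"cycle"` or `"trial"`: the step granularity the parameters
#'   refer to (one cycle = four trials).
#' @return object of class `ss_params` (named list).
#' @export
model_params <- function(A, b, d = 1, level = c("cycle", "trial")) {
  level <- match.arg(level)
  bd <- ss_bounds()
  chk <- function(v, nm) {
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) ||
        v < bd[[nm]][1] || v > bd[[nm]][2]) {
      stop(sprintf("%s = %s outside bounds [%g, %g]", nm,
                   format(v), bd[[nm]][1], bd[[nm]][2]))
    }
  }
  chk(A, "A"); chk(b, "b"); chk(d, "d")
  structure(list(A = A, b = b, d = d, level = level), class = "ss_params")
}

#' @export
print.ss_params <- function(x, ...) {
  cat(sprintf("state-space parameters (%s level): A = %.4f, b = %.4f, d = %.3f\n",
              x$level, x$A, x$b, x$d))
  invisible(x)
}

#' Engagement profile for time-varying error sensitivity
#'
#' A multiplier m(n) on error sensitivity, indexed from the first clamped
#' step (n = 1 at clamp onset), used to model attentional-engagement effects
#' on learning. `constant` gives m(n) = m0; `geometric_decay` gives
#' m(n) = m0 + boost * decay^n, an initial boost that decays back to m0.
#'
#' @param kind `"constant"` or `"geometric_decay"`.
#' @param m0 baseline multiplier (>= 0).
#' @param boost amplitude of the decaying boost.
#' @param decay per-step decay ratio in [0, 1).
#' @return object of class `engagement_profile`.
#' @examples
#' engagement_multiplier(engagement_profile("geometric_decay",
#'                                          boost = 0.35, decay = 0.9), 1)
#' @export
engagement_profile <- function(kind = c("constant", "geometric_decay"),
                               m0 = 1, boost = 0, decay = 0.9) {
  kind <- match.arg(kind)
  if (m0 < 0) stop("m0 must be nonnegative")
  if (kind == "geometric_decay" && (decay < 0 || decay >= 1)) {
    stop("decay must be in [0, 1)")
  }
  if (m0 + min(0, boost) < 0) stop("engagement multiplier would be negative")
  structure(list(kind = kind, m0 = m0, boost = boost, decay = decay),
            class = "engagement_profile")
}

#' Evaluate an engagement multiplier
#'
#' @param profile an [engagement_profile()].
#' @param n step index (>= 1), counted from clamp onset.
#' @return numeric vector of multipliers m(n).
#' @export
engagement_multiplier <- function(profile, n) {
  stopifnot(inherits(profile, "engagement_profile"), all(n >= 1))
  m <- if (profile$kind == "constant") {
    rep(profile$m0, length(n))
  } else {
    profile$m0 + profile$boost * profile$decay^n
  }
  if (any(m < 0)) stop("engagement multiplier negative at some step")
  m
}

#' Simulate the single-rate state-space model over a schedule
#'
#' Steps through the schedule applying the state update
#' x_{n+1} = A x_n + b m(n) e_n. The sensory prediction error is
#' e_n = r_n - y_n on rotation/veridical steps (r_n = 0 for veridical
#' feedback), a fixed angular offset on error-clamp steps (independent of
#' the motor output), and 0 on no-feedback steps (retention-only decay).
#' Across a set break, retention becomes A^d for the following step. The
#' motor output is y_n = -x_n + eps, eps ~ N(0, noise_sd^2); output noise
#' feeds back into the error only on feedback-contingent (veridical) steps.
#'
#' Hand angles are reported in the adjusted convention: positive = the
#' direction of adaptation away from the clamp, regardless of clamp sign
#' (for a counterclockwise clamp this is clockwise, the raw positive
#' direction).
#'
#' @param params an [model_params()] object.
#' @param schedule a `clamp_schedule` (trial level) or the result of
#'   [schedule_cycles()] (cycle level); granularity should match
#'   `params$level`.
#' @param clamp_deg clamp magnitude in degrees (default 45).
#' @param engagement an [engagement_profile()] or `NULL` (constant 1).
#' @param noise_sd output noise standard deviation in degrees (per step).
#' @param seed integer seed, or `NULL`.
#' @return data.frame with columns `step`, `cycle`, `feedback`,
#'   `post_break`, `x` (internal state, model coordinates), `error`
#'   (model-coordinate e_n), `y_raw` (motor output, clockwise-positive) and
#'   `hand_angle` (adjusted, adaptation-positive).
#' @examples
#' sch <- schedule_cycles(make_schedule(seed = 1))
#' sim <- simulate_state_space(model_params(0.92, 0.02), sch)
#' max(sim$hand_angle)  # approaches 0.02 * 45 / 0.08 = 11.25
#' @export
simulate_state_space <- function(params, schedule, clamp_deg = 45,
                                 engagement = NULL, noise_sd = 0,
                                 seed = NULL) {
  stopifnot(inherits(params, "ss_params"))
  if (inherits(schedule, "clamp_schedule") && params$level != "trial") {
    warning("trial-level schedule simulated with ", params$level,
            "-level parameters")
  }
  n <- nrow(schedule)
  stopifnot(n >= 1, clamp_deg >= 0)
  feedback <- schedule$feedback
  post_break <- schedule$post_break
  clamp_sign <- schedule$clamp_sign
  sgn <- clamp_sign[feedback == "clamp"][1]
  if (is.na(sgn)) sgn <- -1L

  eps <- if (noise_sd > 0) {
    with_seed(seed, stats::rnorm(n, 0, noise_sd))
  } else {
    numeric(n)
  }

  is_clamp <- feedback == "clamp"
  first_clamp <- if (any(is_clamp)) which(is_clamp)[1] else Inf
  m <- rep(1, n)
  if (!is.null(engagement) && is.finite(first_clamp)) {
    idx <- which(seq_len(n) >= first_clamp)
    m[idx] <- engagement_multiplier(engagement, idx - first_clamp + 1)
  }

  x <- numeric(n)
  y <- numeric(n)
  e <- numeric(n)
  xi <- 0
  A <- params$A; b <- params$b; d <- params$d
  for (i in seq_len(n)) {
    x[i] <- xi
    y[i] <- -xi + eps[i]
    e[i] <- switch(feedback[i],
      veridical = -y[i],                      # r = 0 rotation step
      clamp = as.numeric(clamp_sign[i]) * clamp_deg,
      none = 0)
    if (i < n) {
      a_step <- if (post_break[i + 1]) A^d else A
      xi <- a_step * xi + b * m[i] * e[i]
    }
  }

  data.frame(
    step = seq_len(n),
    cycle = schedule$cycle,
    feedback = feedback,
    post_break = post_break,
    x = x,
    error = e,
    y_raw = y,
    hand_angle = -as.numeric(sgn) * y,
    stringsAsFactors = FALSE
  )
}

#' Closed-form asymptotic hand angle under a constant clamp
#'
#' The fixed point of the update under a constant clamp of magnitude c with
#' constant engagement m is b m c / (1 - A) in the adjusted (adaptation-
#' positive) convention; the noiseless simulated trajectory
#' y_n = y* (1 - A^n) converges to it from rest.
#'
#' @param params an [model_params()] object (A < 1 required).
#' @param clamp_deg clamp magnitude in degrees.
#' @param m constant engagement multiplier.
#' @return asymptotic hand angle in degrees.
#' @examples
#' steady_state(model_params(0.917, 0.020), 45)  # 10.84
#' @export
steady_state <- function(params, clamp_deg = 45, m = 1) {
  stopifnot(inherits(params, "ss_params"))
  if (params$A >= 1) stop("steady state undefined for A >= 1 (divergent)")
  params$b * m * clamp_deg / (1 - params$A)
}

#' Convert model parameters between trial and cycle level
#'
#' With four trials per cycle the expected relationship is
#' A_cycle = A_trial^4 and b_cycle = 4 b_trial; d is unchanged. If a
#' converted parameter falls outside the fitting bounds it is clipped with
#' a warning and flagged.
#'
#' @param params an [model_params()] object.
#' @param to `"trial"` or `"cycle"` (must differ from `params$level`).
#' @return converted `ss_params`; attribute `clipped` is TRUE if clipping
#'   occurred.
#' @export
convert_level <- function(params, to = c("cycle", "trial")) {
  to <- match.arg(to)
  stopifnot(inherits(params, "ss_params"))
  if (params$level == to) stop("parameters already at ", to, " level")
  if (to == "cycle") {
    A <- params$A^4
    b <- params$b * 4
  } else {
    A <- params$A^(1 / 4)
    b <- params$b / 4
  }
  bd <- ss_bounds()
  clipped <- FALSE
  clip <- function(v, r) {
    if (v < r[1] || v > r[2]) {
      clipped <<- TRUE
      min(max(v, r[1]), r[2])
    } else v
  }
  A <- clip(A, bd$A)
  b <- clip(b, bd$b)
  if (clipped) warning("converted parameters clipped to bounds")
  out <- model_params(A, b, params$d, level = to)
  attr(out, "clipped") <- clipped
  out
}
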