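# shared fixtures: the default experiment schedule and reduced sampler
# settings that keep MCMC-based tests quick while remaining well mixed

default_schedule <- function(seed = 1L, clamp_sign = -1L) {
  make_schedule(clamp_sign = clamp_sign, seed = seed)
}

default_cycles <- function(seed = 1L) schedule_cycles(default_schedule(seed))

quick_sampler <- function(seed = 1L) {
  sampler_config(chains = 2, iterations = 2500, warmup = 500, seed = seed)
}

tiny_sampler <- function(seed = 1L) {
  sampler_config(chains = 2, iterations = 1200, warmup = 200, seed = seed)
}

# independent R-only re-implementation of the window prediction used as a
# brute-force oracle against the compiled kernel
oracle_predict <- function(A, b, d, feedback, post_break, clamp_deg,
                           engagement = rep(1, length(feedback))) {
  K <- length(feedback)
  p <- numeric(K)
  pn <- 0
  for (i in seq_len(K)) {
    p[i] <- pn
    if (i < K) {
      a <- if (post_break[i + 1]) A^d else A
      pn <- switch(feedback[i],
        clamp = a * pn + b * engagement[i] * clamp_deg,
        none = a * pn,
        veridical = (a + b * engagement[i]) * pn)
    }
  }
  p
}
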