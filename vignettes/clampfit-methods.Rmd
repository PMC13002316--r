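---
title: "Modelling implicit adaptation under clamped feedback: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling implicit adaptation under clamped feedback}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clampfit)
```

## The experiment this package models

In an error-clamp reaching experiment, participants make fast center-out
reaches to targets in the four cardinal directions while a cursor provides
feedback. During the clamp phase the cursor's angular path is fixed at
±45° from the target regardless of where the hand actually goes, so the
sensory prediction error (SPE) it delivers is independent of behaviour.
Although participants are told to ignore the cursor, their reach direction
drifts steadily away from the clamp — implicit adaptation. Four trials, one
per target direction, form a *cycle*, the unit of analysis. The standard
schedule is 10 cycles of veridical feedback, 40 cycles of clamped feedback,
one no-feedback cycle (the aftereffect probe) and 20 washout cycles, with
short set breaks where the feedback regime changes.

`clampfit` implements the full modelling-and-inference pipeline for such
experiments: a generative simulator (schedules, participants, behaviour,
raw trajectories, concurrent visual-task reports), trajectory
preprocessing, state-space model fitting, parameter-recovery diagnostics,
Bayesian group inference and bootstrap time-course contrasts. Because the
simulator is a first-class module, every downstream stage is testable
without access to any human dataset.

## The single-rate state-space model

The internal state $x_n$ is the learner's estimate of the visuomotor
mapping at step $n$ (trial or cycle). It evolves as

$$x_{n+1} = A\,x_n + b\,e_n,$$

where $A \in [0.01, 0.999]$ is retention (the fraction of the state
carried to the next step), $b \in [0.001, 0.75]$ is error sensitivity (the
update gain on the SPE) and $e_n$ is the error. Motor output is
$y_n = -x_n + \varepsilon$, $\varepsilon \sim N(0, \sigma^2)$. On
rotation/veridical trials $e_n = r_n - y_n$ (with $r_n = 0$ for veridical
feedback); on clamp trials $e_n$ is the fixed clamp offset, independent of
output; on no-feedback trials we take $e_n = 0$, the standard
retention-only convention (the aftereffect prediction is then $A^d x$
across the set break). Across a set break retention becomes $A^d$,
$d \in [1, 2]$, for exactly one step, modelling time-dependent forgetting
during the pause.

Under a constant clamp $c$ the noiseless trajectory from rest is the
geometric series $y_k = y^\ast(1 - A^{k-1})$ with asymptote
$y^\ast = b\,c/(1-A)$ — the quantity the package's acceptance script
recomputes from each group's reported parameters. Internally the clamp
error is stored with the sign that makes reported hand angles positive in
the direction of adaptation; users only ever see the adjusted convention.

With four trials per cycle, parameters convert between levels as
$A_{cycle} = A_{trial}^4$ and $b_{cycle} = 4\,b_{trial}$. This conversion
matches the early trajectory but not the asymptote exactly
($4(1-A^{1/4}) \ne 1-A$ away from $A = 1$); the package treats the level
of every parameter set explicitly, and `convert_level()` clips (with a
warning) when a converted value leaves the bounds.

The engagement variant multiplies error sensitivity by a profile $m(n)$,
indexed from clamp onset: a constant profile ($m_0$), or a geometric decay
$m(n) = m_0 + \text{boost}\cdot\text{decay}^n$ modelling an attentional
boost that wears off. With $A = 0.92$, $b = 0.02$: $m \equiv 1$ is the
single-task baseline; $m(n) = 1 + 0.35\cdot0.9^n$ produces a transient
enhancement that converges back to baseline; constant $m = 1.10$ or
$m = 1.35$ produce persistent separation (asymptote scaled by $m$). These
are the scenario parameters the acceptance suite checks qualitatively.

## Fitting

Per participant, $(A, b, d)$ minimise the mean-squared error between the
noiseless model prediction (initial state fixed at 0, because the series
is baseline-adjusted) and the observed hand-angle series over the fit
window, by default cycles 11–51 (clamp plus aftereffect; washout is not
fit, since the model section defines errors only for rotation and clamp
trials and the treatment of washout is a user choice). Optimisation is
box-constrained quasi-Newton (`optim` L-BFGS-B, numeric gradients) from
200 uniform random starts within the bounds — the published protocol; the
estimate is the lowest-MSE run. Start draws are blocked per start so that
enlarging `n_starts` under the same seed extends, never reshuffles, the
start set, which makes "more starts never worse" a testable invariant.
The residual MSE absorbs the output noise, which is therefore not an
explicit parameter. $d$ enters the objective only through set breaks
inside the window (the default window contains one, into the aftereffect
cycle); with no break in the window it is fixed at 1 and flagged as not
estimated. Missing cycles are omitted from the objective, never
interpolated. The prediction kernel is compiled (Rcpp), which keeps the
multi-start loops and the recovery experiment fast on one CPU.

The objective surface has a well-known degeneracy: combinations with equal
$b\,c/(1-A)$ produce similar late-window predictions, so estimation error
moves $\hat A$ and $\hat b$ in opposite directions along a valley
(`degeneracy_map()` visualises it). Two consequences are built into the
design: reduced-start fits (10–20 starts) are adequate for the smooth
cycle-level objective (the tests verify identifiability directly), and any
observed negative correlation between $\hat A$ and $\hat b$ must be
compared against the fitting-induced bias, which is what the recovery
module does.

## The synthetic-data generator

The generator's defaults are the study conditions; they are set once and
are not tuning knobs.

* **Schedule**: 10/40/1/20 cycles of veridical/clamp/none/veridical
  feedback, cycle size 4, uniform within-cycle target permutation (the
  published schedule says only "pseudorandom"), set-break flags at phase
  transitions, clamp direction counterbalanced across participants.
* **Participants**: $(\mathrm{logit}\,A, \log b)$ bivariate normal with a
  requested correlation, back-transformed and rejection-resampled to the
  fitting bounds. The population model is not stated in the literature;
  this choice respects the bounds and keeps the correlation interpretable.
  `mean_A` and `mean_b` are medians of the resulting skewed population;
  transformed-scale dispersions are delta-method matched so natural-scale
  standard deviations approximate `sd_A` and `sd_b`.
* **Dispersions**: `sd_A = 0.05`, `sd_b = 0.012`. Steady states
  $b\cdot45/(1-A)$ then span roughly 0.5–30°, matching the wide individual
  differences in late-learning adaptation seen in clamp cohorts.
* **Noise**: `noise_sd_deg = 3.5` is *per-trial* reach-direction noise,
  the typical single-reach directional variability in this paradigm;
  four-trial cycle means then carry about 1.75°, and cycle-level
  simulation uses `noise_sd_deg / 2`. Reported residual noise is not
  available per group (it is absorbed by the residual MSE), so this is a
  documented field-typical choice.
* **Set-break decay**: `d = 1.5`, mid-bounds, as no value is reported.
* **Visual task**: report correctness is Bernoulli per trial at
  epoch-specific rates (baseline 0.72, onset 0.53, early 0.66, late 0.66
  by default — the canonical dual-task pattern); the letter stream itself
  is not rendered because the analysis consumes only correct/incorrect
  counts. Chance is 1/3 for the three-option report.
* **Trajectories**: minimum-jerk radial profiles rotated by the requested
  hand angle, 200 Hz, 5 cm target distance, 6 cm amplitude (shooting
  movements overshoot the target). Requested RT/MT are timed against the
  event detector: the generator solves jointly for movement start and
  duration so the 1 cm/s speed threshold is crossed at RT and the 5 cm
  radius at RT + MT, making the kinematic round trip exact to one sample.
  Movement times are truncated at 155 ms: faster reaches are smeared so
  strongly by the 10 Hz low-pass filter that detected event times no
  longer reflect programmed ones (we measured the transition empirically;
  it is sharp, between 140 and 155 ms).

What the generator does *not* emulate: online corrections mid-reach,
explicit re-aiming, trial-to-trial target-direction biases, attention or
arousal dynamics beyond the engagement multiplier, and participant-level
heterogeneity in report accuracy. Passing tests therefore demonstrate
correctness of the pipeline under the stated generative assumptions, not
that real data satisfy those assumptions.

## Preprocessing

Raw 200 Hz stylus paths are low-pass filtered (8th-order Butterworth,
10 Hz cutoff) forward and backward, so event times are not lagged; this
doubles the effective order, and the signal is odd-reflection padded
before filtering because high-order `filtfilt` otherwise produces large
boundary transients (the numerical floor after padding is ~10⁻³ cm).
Trajectories are rotated rigidly to the common 90° axis. Reach onset is
the first sample whose speed (central differences of filtered positions)
strictly exceeds 1 cm/s; offset is the first sample beyond the 5 cm target
radius; hand angle is the signed angle (clockwise positive) between the
onset→target and onset→offset vectors. Straightness is chord over path
length — the reported value's formula is not given in the source
literature, so this standard definition is a documented choice.

Exclusions follow four rules: amplitude under 5 cm; hand angle beyond ±90°
or more than 25° from a 10-point moving median (centered — 5 before, 4
after — truncated at the edges, computed over trials that survived the
amplitude and ±90° checks, in chronological order); RT above the
participant's 97.5th percentile from a Gaussian KDE (Silverman bandwidth,
CDF inverted on a fine grid; empirical percentile fallback with a warning
below 20 trials); MT over 500 ms. The KDE threshold is computed per
participant over all trials. Note the percentile rule by construction
flags about 2.5% of clean trials — tests assert the flagged set equals a
brute-force recomputation rather than pretending the rule only catches
gross outliers. Valid trials are averaged per cycle; learning and
aftereffect cycles are baseline-adjusted by subtracting the mean over
cycles 6–10; clockwise-clamp participants' angles are mirrored before
aggregation so positive always means adaptation.

## Bayesian inference

Point estimates are posterior medians; uncertainty is the 89% highest
density interval (the shortest interval containing 89% of draws), and
directional claims are posterior probabilities. The sampler configuration
defaults to 4 chains × 3,500 iterations with 1,000 warm-up; convergence is
checked after every fit via split R-hat (< 1.01) and effective sample
size, with a warning raised otherwise.

* **Group means and contrasts** use a Student-t likelihood
  $y_i \sim t_\nu(\mu, \sigma)$. Priors are reconstructions, exposed in
  configuration: $\mu \sim N(\bar y, 30°)$ (wide, centred on the sample
  statistic), inverse-gamma on $\sigma^2$ moment-matched to the sample
  variance, and $\nu \sim 1 + \mathrm{Exp}(29)$. The sampler is an exact
  scale-mixture Gibbs sampler written for this package (conjugate updates
  for $\mu$, $\sigma^2$ and the latent weights; a two-scale Metropolis
  step on $\log(\nu - 1)$). A generic-engine fit (JAGS) of the same model
  serves as an independent cross-check in the test suite. The dedicated
  sampler is roughly two orders of magnitude faster, which is what makes
  the full 1,000-dataset HDI-calibration test feasible; at that size the
  ±3 percentage-point calibration band equals three binomial standard
  errors. Standardized effect sizes divide the mean difference by
  $\sqrt{(\sigma_a^2 + \sigma_b^2)/2}$ draw-wise, the common two-group
  convention; the source literature does not print its formula.
* **Report accuracy** is a hierarchical binomial model in JAGS:
  participant random intercepts plus fixed epoch effects on the logit
  scale (baseline as reference), epoch-effect priors $N(0, 1.5)$,
  intercept-mean prior $N(0, 1.5)$, intercept-SD uniform(0, 3). Reported
  epoch accuracies are for the population-typical participant; odds
  ratios are $e^{\beta_e}$.
* **Correlations** use a bivariate normal on standardized pairs with a
  uniform(−1, 1) prior on $r$ (JAGS).
* **The joint (A, b) group model** is a bivariate normal on
  $(\mathrm{logit}\,A_i, \log b_i)$ with wide normal priors on the means,
  uniform scale priors and a uniform(−1, 1) correlation prior
  (separation parameterisation rather than a Wishart). Group means are
  back-transformed location parameters; the correlation is reported on
  the transformed scale — the scale used in the source analyses is
  unstated, which is a documented divergence risk, though for the
  dispersions involved the two scales differ by only a few hundredths.
  Ordering probabilities (e.g. $\Pr(b_{ST} < b_{DT} < b_{DT_F})$) are
  computed draw-wise from the independent group posteriors, and posterior
  predictive trajectories propagate joint draws through the noiseless
  model.
* **Type S/M errors** marginalise over posterior uncertainty: each
  simulation draws a true effect from the posterior, simulates a replicate
  two-group experiment at the same group size with the posterior scale as
  noise, and records sign disagreement with the posterior median and the
  exaggeration ratio. The precise published algorithm lives in external
  supplementary material; this is one reasonable reading of
  "marginalises over posterior uncertainty", documented as such.
* **Concordance** $\rho_c = 2\,\mathrm{cov}(x,y)/(\mathrm{var}(x) +
  \mathrm{var}(y) + (\bar x - \bar y)^2)$ uses population moments; the
  Bayesian flag wraps it over Dirichlet-weighted (Bayesian bootstrap)
  draws of the moments.

The published analyses used a Hamiltonian sampler; `SamplerConfig` keeps
the `adapt_delta` / `max_treedepth` fields for configuration
compatibility, but the Gibbs-based samplers here do not use them, and
divergence counts do not exist for Gibbs sampling — R-hat and effective
sample size are the operative diagnostics.

## Parameter recovery

`run_recovery()` asks whether an observed negative $\hat A$–$\hat b$
correlation could be produced by fitting alone: A and b are sampled
*independently* (generating correlation 0), trajectories are simulated
with realistic noise, refit, and the Pearson correlation of the recovered
estimates collected across replicate cohorts (default cohort size 24; the
published description of one correlation per simulated experiment is
ambiguous about cohort composition, and replicated cohorts of the study's
size is the documented reading). Marginal sources default to the
dual-task group location with the generator's participant-level
dispersions; with narrower (posterior-of-the-mean) sources the recovered
correlation is dominated by the fitting degeneracy (median near −0.8 in
our measurements) and the diagnostic loses its meaning — the bias would
swamp any signal. Noise defaults to the cycle-level residual scale
(1.75°), or resamples supplied residual vectors. The key output is the
89% interval of recovered correlations and the proportion at least as
extreme as the observed value.

## Bootstrap time-course contrasts

Participant series are smoothed with a five-cycle centered moving average
(truncated at the edges), participants are resampled with replacement
within group (10,000 iterations by default), and the per-cycle difference
of group means is summarised by its median and 89% interval — computed
with the same shortest-interval routine as the posterior summaries, with
a percentile option since usage varies. Cycles whose interval excludes 0
are flagged, and contiguous flagged runs are reported to distinguish
sustained from transient divergence. Whether smoothing preceded baseline
adjustment in the source analyses is unstated; here smoothing operates on
already-adjusted series. Note that with an 89% interval, identical groups
are flagged at roughly 11% of cycles by construction (slightly more at
small samples, where the bootstrap runs anti-conservative); the tests
assert this calibration rather than a near-zero false-positive rate.

## Problem sizes and numerical choices

The test suite runs the full 1,000-dataset HDI calibration, a
200-participant noisy-identifiability check, a 200-replicate recovery
experiment and reduced-length MCMC configurations for the JAGS models
(2 chains, a few thousand draws) — sizes chosen so the entire suite
completes in a few minutes on one CPU while keeping every Monte-Carlo
acceptance band at three standard errors or wider. Optimiser tolerances
are `optim` L-BFGS-B defaults with `factr = 1e7`; noiseless fits recover
parameters to ~10⁻³, and the tests assert parameter accuracy rather than
machine-zero MSE. Degenerate inputs are handled explicitly: zero-variance
correlation inputs, all-missing series in a cohort, cycles with no valid
trials, empty fit windows and out-of-bound conversions all raise or flag
rather than silently proceeding.

## Known limitations

* The washout error convention ($e = -y$ under veridical feedback with
  the output equation $y = -x$) implies washout decay at rate $A + b$;
  it is the literal published model and washout is outside the default
  fit window, but users fitting washout should be aware of it.
* Trial/cycle parameter conversion is exact only in the $A \to 1$ limit;
  concordance between levels is high on clean data (the acceptance suite
  checks > 0.95) but degrades with noise, particularly for $b$.
* The joint (A, b) correlation is estimated on point estimates, not by
  joint hierarchical fitting of the trajectories, mirroring the source
  pipeline; fitting-induced bias must therefore always be read against
  the recovery experiment.
* Event detection for reaches faster than ~150 ms is systematically
  biased by the 10 Hz filter; the generator refuses to produce them by
  default rather than pretending the round trip holds there.
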