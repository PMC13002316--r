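Package: clampfit
Title: State-Space Modelling of Implicit Visuomotor Adaptation Under
    Error-Clamp Feedback
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation, preprocessing, model fitting and Bayesian inference
    for error-clamp visuomotor adaptation experiments. Generates complete
    synthetic experiments (trial schedules, participant parameters, reach
    trajectories, dual-task report accuracy), preprocesses raw 2-D reach
    trajectories to cycle-level baseline-adjusted hand angles, fits the
    single-rate state-space model of motor adaptation by multi-start
    constrained mean-squared-error minimisation, runs parameter-recovery
    diagnostics for the retention/error-sensitivity degeneracy, and performs
    robust Bayesian group comparisons, hierarchical binomial accuracy
    modelling, joint group-level parameter estimation with correlations,
    and bootstrap time-course contrasts, all summarised with 89% highest
    density intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    rjags,
    coda,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
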