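# Study conditions for the synthetic experiments: three groups of 24, the
# standard 71-cycle schedule (10 veridical / 40 clamp / 1 no-feedback /
# 20 washout cycles), 45-degree clamp. Group (A, b) locations are the
# reported posterior medians; dispersions and noise are the generator
# defaults (see the methods vignette).
master_seed: 20260301
clamp_deg: 45
groups:
  ST:
    mean_A: 0.917
    mean_b: 0.020
    corr_Ab: -0.30
  DT:
    mean_A: 0.897
    mean_b: 0.026
    corr_Ab: -0.68
  DT_F:
    mean_A: 0.893
    mean_b: 0.033
    corr_Ab: -0.58
n_participants: 24
rsvp:
  # DT-style epoch accuracies; ST performs the prompted keypress at
  # near-ceiling, DT_F recovers fully by late learning
  DT: {baseline: 0.72, onset: 0.53, early: 0.66, late: 0.66, other: 0.72}
  DT_F: {baseline: 0.72, onset: 0.49, early: 0.66, late: 0.72, other: 0.72}
  ST: {baseline: 0.95, onset: 0.95, early: 0.95, late: 0.95, other: 0.95}
fit:
  n_starts: 50
bootstrap:
  n_iterations: 5000
recovery:
  n_replicates: 50
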