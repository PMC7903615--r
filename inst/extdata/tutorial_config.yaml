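# Tutorial pipeline: simulate a paired wound-healing + fibrosis study with
# one planted Areg-pattern gene at zero noise, screen both courses and
# intersect. Pass an output directory to run_pipeline().
simulate:
  seed: 1
  n_genes: 60
  n_replicates: 3
  noise_log2_sd: 0.0
  wound_timepoints_h: [0, 6, 12, 24, 72, 120]
  fibrosis_timepoints_h: [0, 72, 168, 240]
  class_proportions:
    TRANSIENT: 0.10
    SUSTAINED: 0.10
    FLAT: 0.80
  peak_folds:
    TRANSIENT: 10
    SUSTAINED: 10
  overlap:
    G000001: SUSTAINED
  alias:
    G000001: Areg
screen:
  induction_fold: 2.0
  induction_timepoints_h: [12, 24]
  return_timepoint_h: 3d
  return_band: 0.2
  alpha: 0.01
  test_method: welch_t
  fibrosis_baseline: matched_control
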