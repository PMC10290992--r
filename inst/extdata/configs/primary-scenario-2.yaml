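# Single arrhythmic event (early return to systole) at phantom scale:
# two-stage vs random-walk Kalman filtering under golden-angle radial
# undersampling.
phantom:
  N: 32
  T: 20
  seed_train: 1
  seed_test: 2
scenario:
  kind: arrhythmia
  n_cycles: 5
  truncate_at_phase: 12
  affected_cycle: 2
sampling:
  kind: radial
  n_spokes: 5
  noise_sigma: 0.02
  seed: 7
recon:
  variants: [two_stage, random_walk]
  rescale: true
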