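# Default experiment configuration: the clinical acquisition and cohort
# conditions. Any omitted key falls back to the package default.
cohort:
  n_cae: 42
  n_hc: 50
  alps_cae: [1.45, 0.36]
  alps_hc: [1.66, 0.30]
  age_cae: [8.31, 2.12]
  age_hc: [8.44, 1.94]
  age_bounds: [4, 12]
  duration: [10.71, 4.97]
  frequency: [7.71, 2.00]
  r_alps_age_cae: 0.766
  r_alps_age_hc: 0.651
  r_alps_duration: -0.48
  r_alps_frequency: 0
acquisition:
  n_directions: 30
  b: 1000
  n_b0: 1
  s0: 1000
  snr: 30
roi:
  diameter: 5
seed: 7
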