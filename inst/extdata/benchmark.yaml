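seed: 101
generator:
  n_reaches: 400
  pond_fraction: 0.15
  source_mode: variable
  topology: recursive
removal:
  nu_s_small: 0.2
  nu_s_large: 0.05
  nu_p: 0.02
  cutoff_m3s: 2.83
  region: synthetic
thresholds:
  lowess_span: 0.5
  grid_size: 200
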