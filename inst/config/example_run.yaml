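# Example pipeline configuration for the piop.R command-line front end.
# Field names mirror phantom_config(), network_spec() and training_config().
seed: 42
out_dir: run

phantom:
  n_cases: 6
  grid_shape: [32, 32, 16]
  spacing_mm: [2, 2, 2]
  tumor_suv_range: [4, 6]
  tumor_radius_range_mm: [5, 8]
  ctv_margin_mm: 4
  delivered_dose_gy: 20
  response_alpha_per_gy: [0.08, 0.08]
  noise_sd_suv: 0
  split: {train: 0.5, val: 0.25, test: 0.25}

network:
  filters_per_layer: [8, 16, 16, 16, 16, 16, 8, 1]

training:
  epochs: 60
  learning_rate: 0.002
  batch_size: 4

evaluation:
  modes: [2D, 3D]
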