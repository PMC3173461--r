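# Default pipeline configuration: fully synthetic end-to-end run emulating
# the dye-swap Pi withdrawal/re-supply design.
seed: 1
out_dir: "pistatus_out"
simulate:
  n_genes: 2000
  frac_responsive: 0.1
  effect_fold: 2.0
  noise_sd: 0.25
  dye_bias: [0.0]
  frac_absent: 0.01
  frac_low_signal: 0.02
  field:
    n_per_class: 15
    attenuation: 0.8
    noise_sd: 0.25
preprocess:
  lowess_span: 0.35
  control_floor: 10
  raw_floor: 50
  raw_floor_timepoints: 5
  flat_band: [0.8, 1.2]
  absent_frac: 0.5
de:
  alpha: 0.01
  fc_threshold: 1.5
  min_timepoints: 2
  n_groups: 8
enrich:
  annotation: null
classify:
  sizes: [25, 50, 100, 200, 250, 500, 1000, 1500, 2000]
  kernels: [poly1, poly2, poly3, rbf]
  C: 1.0
  k: 200
  kernel: poly1
  replete_days: [0, 31]
transfer:
  map: null
  reference_expr: null
  reference_meta: null
  test_expr: null
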