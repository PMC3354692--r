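# Example trabfe pipeline configuration.
# Three synthetic femoral-head cores spanning the observed BV/TV range,
# coarsened by all four schemes and regressed against structural indices.
seed: 1
output_dir: trabfe_out
material:
  e_tissue_gpa: 10
  nu: 0.3
load:
  strain: 0.008
solver:
  type: auto
  tol: 1.0e-8
log_fit_dmax_um: 300
methods:
  H: [72, 108, 144]
  FL: [72, 108, 144, 216, 288]
  FS: [72, 108, 144, 216, 288]
  FT: [72, 144, 216, 288]
phantoms:
  - kind: grf
    shape: [24, 24, 40]
    target_bvtv: 0.30
    correlation_length: 100
    seed_offset: 4
  - kind: grf
    shape: [24, 24, 40]
    target_bvtv: 0.40
    correlation_length: 100
    seed_offset: 2
  - kind: grf
    shape: [24, 24, 40]
    target_bvtv: 0.50
    correlation_length: 100
    seed_offset: 3
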