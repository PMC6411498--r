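# Example pipeline configuration: a small synthetic dose cohort analysed at
# desk scale.  Full-scale defaults are grid_nu 100, grid_nv 150 (15,000
# vertices per side) and n_perm 10000.
cohort:
  group_sizes: {NC: 6, HT: 6, HM: 6}
  effect_magnitudes: {NC: 0.0, HT: 0.6, HM: 1.2}
  patch_center: [0.45, 0.0]
  patch_radius: 0.3
  subject_variability_sd: 0.3
  vertex_noise_sd: 0.05
  template_args: {n_rings: 30, n_around: 20}
  seed: 7
grid_nu: 20
grid_nv: 75
n_perm: 1000
alpha: 0.05
seed: 1
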