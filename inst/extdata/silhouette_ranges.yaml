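# Default parameter ranges for the synthetic carrot silhouette generator.
# Units: px for lengths/widths, degrees for angles, 0-255 intensity units
# for noise_sd; curvature and branch/break points are fractions of length.
length: [350, 450]
base_width: [60, 90]
taper: [0.8, 1.4]
angle: [-25, 25]
noise_sd: 5
regular:
  curvature: [0, 0.02]
irregular:
  type_weights:          # curved / forked / broken
    curved: 0.5
    forked: 0.3
    broken: 0.2
  curved_curvature: [0.08, 0.25]
  residual_curvature: [0, 0.02]   # curvature of forked/broken samples
  n_branches: [2, 3]
  fork_point: [0.45, 0.65]
  break_point: [0.35, 0.65]
  branch_spread_deg: 14
rgb:
  carrot: [205, 130, 50]
  background: [235, 233, 230]
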