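# Default beam-model configuration for the LAC field-size QA method.
#
# The output-factor table below is SYNTHETIC: a plausible monotone,
# saturating small-field curve normalized to 1 at the 60 mm aperture. It is
# a stand-in for machine commissioning data and is flagged as such so that
# reports carry the mark.
chamber:
  active_diameter_mm: 81.6
  plane_sad_mm: 791
  window_mm: 3.47
profile:
  penumbra_mm: 3
  flatness: 0
  detune_level: 0
of_table_synthetic: true
of_table:
  - [5.0, 0.679997]
  - [7.5, 0.730412]
  - [10.0, 0.773087]
  - [12.5, 0.809211]
  - [15.0, 0.839790]
  - [20.0, 0.887584]
  - [25.0, 0.921830]
  - [30.0, 0.946368]
  - [35.0, 0.963951]
  - [40.0, 0.976549]
  - [50.0, 0.992044]
  - [60.0, 1.000000]
simulation:
  seed: 1
  n_repeats: 5
  mu: 100
  output_drift_sd: 0.04
  mu_delivery_sd: 0.04
  aperture_jitter_sd: 0.02
  misalignment: 0
  detune_level: 0
  aperture_offsets: 0
  calibration_drift: 0
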