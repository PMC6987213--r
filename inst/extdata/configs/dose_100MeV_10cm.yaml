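# Water-phantom minibeam-grid dose: 100 MeV, 10 cm air gap, 5x5, 2.9 mm
# fields_T should be set to the scan minimum for this configuration
experiment: dose
seed: 1
nozzle:
  preset: optimized
  air_gap_cm: 10
source:
  energy_MeV: 100
  energy_spread: 0.01
  sigma_x_mm: 4.0
  sigma_y_mm: 4.0
  div_x_mrad: 3.0
  div_y_mrad: 3.0
  r_xx: -1
  r_yy: -1
dose:
  spacing_mm: 2.9
  n_beams: 5
  mode: analytic
  phantom_depth_cm: 10
  fields_T: [0.16, 0.20]
  arrangement: q1_horizontal
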