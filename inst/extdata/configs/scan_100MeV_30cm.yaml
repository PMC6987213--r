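# Quadrupole grid scan: optimised nozzle, 100 MeV, 30 cm air gap
experiment: scan
seed: 1
nozzle:
  preset: optimized
  air_gap_cm: 30
source:
  energy_MeV: 100
  energy_spread: 0.01
  sigma_x_mm: 6.5
  sigma_y_mm: 10.0
  div_x_mrad: 5.0
  div_y_mrad: 5.0
  r_xx: -1
  r_yy: -1
scan:
  field_min_T: 0
  field_max_T: 2
  field_step_T: 0.04
  particles: 100000
  refine_top: 20
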