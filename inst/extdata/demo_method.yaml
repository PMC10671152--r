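# Demonstration method configuration: a 250 x 4.6 mm, 10 um column on a
# system with 1.0 mL dwell volume, run at the calibration design defaults.
length_mm: 250
id_mm: 4.6
particle_um: 10
porosity: 0.68
dwell_ml: 1.0
flow_ml_min: 0.5
temp_c: 20
ternary_fraction: 0
design:
  tG_levels: [20, 60]
  T_levels: [5, 35]
  tC_levels: [0, 0.5, 1]
  phi0: 0.30
  phif: 1.00
  flow_ml_min: 0.5
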