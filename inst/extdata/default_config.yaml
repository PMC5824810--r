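# Default analysis configuration: DOPC bilayer mechanics, confocal/FCS
# calibration, and synthetic-data ground truth mirroring the moderately
# curved (Q3) condition.
mechanics:
  kappa_kBT: 23.1        # DOPC bending modulus
  alpha: 0.9549296586    # 3/pi, non-local over local rigidity
  c0_per_nm: 0           # symmetric bilayer
  thickness_nm: 4
  delta_a0_nm2: 0
  temperature_K: 298.15
fcs:
  r0_nm: 207             # detection-volume waist (reference-dye calibrated)
simulation:
  seed: 1
  n_guvs: 15
  true_kd_nM: 0.68
  true_imax: 1000
  intensity_cv: 0.2
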