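# Analytic 6 MV FFF beam preset for the fixed virtual cone model.
# Units: mm, cGy, MU. Same construction as the 10 MV FFF preset; the
# small-field output-factor falloff is steeper, reflecting the larger
# relative output sensitivity of the 6 MV FFF beam to aperture changes.
energy_label: 6FFF
sigma_penumbra: 1.4
mlc_transmission: 0.012
jaw_transmission: 0.002
leaf_end_offset: 0.4
leaf_side_offset: 0.3
dmu_cal: 0.558
max_dose_rate: 1400
tmr:
  depth: [0, 5, 10, 15, 20, 30, 40, 50, 60, 70, 80, 90, 100, 120, 150, 200, 250]
  value: [0.55, 0.80, 0.94, 1.00, 0.995, 0.965, 0.936, 0.905,
          0.85663, 0.81085, 0.76752, 0.72650, 0.68767, 0.61621, 0.52253,
          0.39702, 0.30166]
of_tables:
  "95/5":
    size: [2, 3, 4, 4.612548, 5.699123, 7, 8, 10, 15, 20, 30, 50, 80, 100]
    value: [0.300, 0.413, 0.497, 0.535, 0.605, 0.672, 0.700, 0.740, 0.800,
            0.840, 0.888, 0.940, 0.982, 1.000]
  "90/10":
    size: [2, 3, 4, 4.612548, 5.699123, 7, 8, 10, 15, 20, 30, 50, 80, 100]
    value: [0.272, 0.382, 0.460, 0.496, 0.560, 0.624, 0.652, 0.694, 0.758,
            0.805, 0.862, 0.925, 0.976, 1.000]
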