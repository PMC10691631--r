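# Analytic 10 MV FFF beam preset for the fixed virtual cone model.
# Units: mm, cGy, MU. The TMR table is anchored so the central-axis dose/MU
# of the nominal field matches the calibration values at the two clinical
# settings (95 cm SSD / 5 cm depth and 90 cm SSD / 10 cm depth, 100 cm SAD);
# output-factor tables are indexed by effective equivalent-square size.
energy_label: 10FFF
sigma_penumbra: 1.6
mlc_transmission: 0.012
jaw_transmission: 0.002
leaf_end_offset: 0.45
leaf_side_offset: 0.33
dmu_cal: 0.547
max_dose_rate: 2400
tmr:
  depth: [0, 5, 10, 15, 20, 23, 30, 40, 50, 60, 70, 80, 90, 100, 120, 150, 200, 250]
  value: [0.50, 0.72, 0.86, 0.94, 0.99, 1.00, 0.985, 0.935, 0.880,
          0.83941, 0.80071, 0.76378, 0.72854, 0.69499, 0.63234, 0.54883,
          0.43339, 0.34226]
of_tables:
  "95/5":
    size: [2, 3, 4, 4.8, 5.778754, 7, 8, 10, 15, 20, 30, 50, 80, 100]
    value: [0.280, 0.400, 0.470, 0.515, 0.550, 0.578, 0.600, 0.640, 0.715,
            0.770, 0.845, 0.920, 0.978, 1.000]
  "90/10":
    size: [2, 3, 4, 4.8, 5.778754, 7, 8, 10, 15, 20, 30, 50, 80, 100]
    value: [0.258, 0.371, 0.436, 0.478, 0.510, 0.536, 0.557, 0.597, 0.678,
            0.738, 0.822, 0.908, 0.972, 1.000]
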