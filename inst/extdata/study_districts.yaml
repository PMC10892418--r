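# Study design for the shipped synthetic sampling campaign.
# Per-district, per-metal distribution targets (min/max/mean in mg/kg,
# CV in percent) and the pooled inter-metal Pearson correlation target
# used on the latent Gaussian scale. Bounding boxes are arbitrary planar
# (projected-metre) extents for the three irrigation districts.
districts:
  Xiaodian:
    n_samples: 35
    bbox: [0, 0, 8000, 8000]
    metals:
      As: {min: 7.80, max: 26.74, mean: 12.33, cv: 27.90}
      Hg: {min: 0.02, max: 0.34, mean: 0.07, cv: 77.16}
      Cd: {min: 0.11, max: 0.69, mean: 0.27, cv: 51.22}
      Cr: {min: 44.32, max: 100.09, mean: 59.15, cv: 22.65}
      Pb: {min: 9.85, max: 42.19, mean: 21.52, cv: 39.25}
      Cu: {min: 18.36, max: 50.84, mean: 30.03, cv: 23.21}
      Zn: {min: 55.00, max: 144.13, mean: 97.18, cv: 24.87}
  Jinyuan:
    n_samples: 35
    bbox: [-9000, 0, -1000, 8000]
    metals:
      As: {min: 0.06, max: 14.63, mean: 9.22, cv: 33.97}
      Hg: {min: 0.001, max: 0.84, mean: 0.16, cv: 127.3}
      Cd: {min: 0.10, max: 0.30, mean: 0.19, cv: 31.71}
      Cr: {min: 48.11, max: 92.12, mean: 67.91, cv: 18.96}
      Pb: {min: 15.60, max: 39.82, mean: 28.42, cv: 23.63}
      Cu: {min: 15.00, max: 41.68, mean: 27.87, cv: 27.90}
      Zn: {min: 56.35, max: 145.47, mean: 81.77, cv: 21.34}
  Qingxu:
    n_samples: 40
    bbox: [-4000, -12000, 4000, -2000]
    metals:
      As: {min: 7.04, max: 18.18, mean: 10.64, cv: 26.00}
      Hg: {min: 0.02, max: 0.34, mean: 0.07, cv: 99.46}
      Cd: {min: 0.03, max: 0.54, mean: 0.18, cv: 44.95}
      Cr: {min: 47.96, max: 96.68, mean: 75.20, cv: 14.53}
      Pb: {min: 15.94, max: 42.02, mean: 22.99, cv: 22.39}
      Cu: {min: 13.38, max: 53.72, mean: 27.49, cv: 29.35}
      Zn: {min: 42.77, max: 124.74, mean: 77.54, cv: 18.68}
correlation:
  As: {As: 1.0, Hg: -0.030, Cd: -0.106, Cr: -0.202, Pb: -0.283, Cu: 0.059, Zn: 0.013}
  Hg: {As: -0.030, Hg: 1.0, Cd: -0.086, Cr: 0.232, Pb: 0.233, Cu: -0.076, Zn: -0.037}
  Cd: {As: -0.106, Hg: -0.086, Cd: 1.0, Cr: 0.058, Pb: 0.085, Cu: 0.369, Zn: 0.498}
  Cr: {As: -0.202, Hg: 0.232, Cd: 0.058, Cr: 1.0, Pb: 0.296, Cu: 0.270, Zn: 0.091}
  Pb: {As: -0.283, Hg: 0.233, Cd: 0.085, Cr: 0.296, Pb: 1.0, Cu: 0.300, Zn: 0.251}
  Cu: {As: 0.059, Hg: -0.076, Cd: 0.369, Cr: 0.270, Pb: 0.300, Cu: 1.0, Zn: 0.392}
  Zn: {As: 0.013, Hg: -0.037, Cd: 0.498, Cr: 0.091, Pb: 0.251, Cu: 0.392, Zn: 1.0}
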