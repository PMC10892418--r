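# Shipped reference values: Taiyuan geochemical backgrounds (mg/kg),
# GB15618-2018 agricultural risk screening standards (mg/kg), Hakanson
# toxic response factors (dimensionless) and instrument detection limits
# (mg/kg, advisory). Identical to the package defaults; kept as a template
# for site-specific overrides.
background:
  As: 7.60
  Hg: 0.03
  Cd: 0.08
  Cr: 57.30
  Pb: 13.80
  Cu: 18.40
  Zn: 56.30
standard:
  As: 25.0
  Hg: 3.4
  Cd: 0.6
  Cr: 250.0
  Pb: 170.0
  Cu: 100.0
  Zn: 300.0
toxicity:
  As: 10.0
  Hg: 40.0
  Cd: 30.0
  Cr: 2.0
  Pb: 5.0
  Cu: 5.0
  Zn: 1.0
detection:
  As: 0.01
  Hg: 0.002
  Cd: 0.6
  Cr: 1.0
  Pb: 2.1
  Cu: 1.2
  Zn: 3.2
igeo_margin: 1.5
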