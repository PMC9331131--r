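# Tryptic proteolysis of bovine beta-lactoglobulin: default model
# configuration. 161 peptide bonds, 15 hydrolyzable trypsin-specific bonds
# (of 18 Lys/Arg sites; K47, K60, K100 carry rate 0 and are excluded).
# Units: rate constants L mg^-1 min^-1 (dimensional block) or dimensionless
# ratios; enzyme concentrations mg/L; wavelengths nm.
substrate:
  name: beta-LG
  total_bonds: 161
  s01_fraction: 0.66666667   # one-stage pool, bond-count proportion 10/15
  s02_fraction: 0.33333333   # two-stage pool, 5/15
  lambda:
    masked: 340       # observed starting fluorescence maximum
    partial: 350      # intermediate level; configurable placeholder
    demasked: 354     # observed asymptotic maximum at high enzyme
  classes:
    - {route: fast, count: 4}              # hydrolysis much faster than demasking
    - {route: one_stage, count: 2, kappa: 0.8}
    - {route: one_stage, count: 2, kappa: 0.4}
    - {route: one_stage, count: 2, kappa: 0.2}
    - {route: two_stage, count: 5, kappa: 0.35}
  bond_annotation:
    - {bond: K8, route: fast}
    - {bond: K69, route: fast}
    - {bond: K75, route: fast}
    - {bond: R148, route: fast}
    - {bond: R40, route: one_stage, kappa: 0.8}
    - {bond: K141, route: one_stage, kappa: 0.8}
    - {bond: K14, route: one_stage, kappa: 0.4}
    - {bond: K70, route: one_stage, kappa: 0.4}
    - {bond: R124, route: one_stage, kappa: 0.2}
    - {bond: K138, route: one_stage, kappa: 0.2}
    - {bond: K77, route: two_stage, kappa: 0.35}
    - {bond: K83, route: two_stage, kappa: 0.35}
    - {bond: K91, route: two_stage, kappa: 0.35}
    - {bond: K101, route: two_stage, kappa: 0.35}
    - {bond: K135, route: two_stage, kappa: 0.35}
    - {bond: K47, route: none, kappa: 0}
    - {bond: K60, route: none, kappa: 0}
    - {bond: K100, route: none, kappa: 0}
kinetics:
  dimensionless:
    epsilon: 1.0      # E/E0, reference enzyme concentration E0 = 10 mg/L
    kappa_m: 0.05     # km/(k1 E0), secondary masking
    kappa2: 0.3       # k2/k1, second- over first-stage demasking
analysis:
  fit_interval: [0.0, 0.05]
  n_points: 51
synth:
  sigma_lambda: 0.2   # nm, additive noise on lambda_max
  sigma_intensity: 0.01
  sigma_dh: 0.001
  seed: 1
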