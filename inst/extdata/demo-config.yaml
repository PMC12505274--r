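seed: 2.0260101e+07
heating_rates:
- 0.5
- 1.0
- 2.0
program:
  start_C: 25.0
  end_C: 160.0
thermo:
  Tg: 58.4
  dCp_molar: 271.4
  molar_mass: 471.68
  Tm_I: 149.9
  Tm_II: 145.9
  dHf_I: 13.5
  dHf_II: 99.7
  dHc: 95.3
conditions:
- name: annealed_-20C_40d
  kinetics:
    Ea: 134000.0
    lnA: 39.6
    'n': 4.7
    alpha0: 1.0e-08
  isothermal:
    t10: 13.6
    'n': 4.7
- name: annealed_25C_40d
  kinetics:
    Ea: 115000.0
    lnA: 32.77
    'n': 4.1
    alpha0: 1.0e-08
  isothermal:
    t10: 18.3
    'n': 4.1
noise:
  heat_flow_sd: 0.0005
  cp_sd: 0.001
  pxrd_sd: 2.0
analysis:
  alphas:
  - 0.05
  - 0.06
  - 0.07
  - 0.08
  - 0.09
  - 0.1
  edge_count: 100.0
  tg_window:
  - 45.0
  - 75.0
  exo_limits:
  - 85.0
  - 138.0
  melt_limits:
  - 139.0
  - 158.0
  dt: 0.05
pxrd:
  grid:
    from: 2.5
    to: 40.0
    step: 0.01
  fwhm: 0.12
  mix: 0.3
  reference_area: 20.0
  centers:
  - 6.8
  - 16.1
  - 16.6
  - 19.0
  - 19.7
  forms:
  - I
  - II
  - I
  - II
  - I
  rel_area:
    annealed_-20C_40d:
    - 0.043
    - 1.0
    - 0.267
    - 0.437
    - 0.064
    annealed_25C_40d:
    - 0.053
    - 1.0
    - 0.287
    - 0.396
    - 0.156
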