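# Healthy closed-loop circulation parameters (package defaults).
# Units: resistance mmHg s/ml, inductance mmHg s^2/ml, capacity ml/mmHg,
# elastance mmHg/ml, durations s, volumes ml.
# Valve R_min is the open-valve resistance consistent with the calibrated
# physiological operating point (see the methods vignette).
T_cycle: 0.8
scenario: healthy
chambers:
  RA: {E_a: 0.06, E_b: 0.07, T_contr: 0.17, T_relax: 0.17, V_0: 10.0, t_onset: 0.65}
  RV: {E_a: 0.55, E_b: 0.05, T_contr: 0.34, T_relax: 0.15, V_0: 30.0, t_onset: 0.0}
  LA: {E_a: 0.07, E_b: 0.09, T_contr: 0.17, T_relax: 0.17, V_0: 10.0, t_onset: 0.65}
  LV: {E_a: 2.75, E_b: 0.08, T_contr: 0.34, T_relax: 0.15, V_0: 15.0, t_onset: 0.0}
valves:
  TV: {R_min: 7.5e-3, R_max: 7.5e+4}
  PV: {R_min: 7.5e-3, R_max: 7.5e+4}
  MV: {R_min: 7.5e-3, R_max: 7.5e+4}
  AV: {R_min: 7.5e-3, R_max: 7.5e+4}
compartments:
  proximal: {R: 3.21e-2, L: 2.50e-3, C: 3.90}     # proximal pulmonary artery
  pa:       {R: 2.50e-4, L: 2.0e-3,  C: 5.0e-4}   # PA block, closed loop only
  micro:    {R: 2.29e-2, L: 1.65e-3, C: 0.25}     # microvasculature and lungs
  ven_pul:  {R: 3.56e-2, L: 5.0e-4,  C: 16.0}     # pulmonary venous system
  art_sys:  {R: 0.64,    L: 5.0e-3,  C: 1.2}      # systemic arterial system
  ven_sys:  {R: 0.26,    L: 5.0e-4,  C: 60.0}     # systemic venous system
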