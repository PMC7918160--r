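# Demo run: a 7-patient, 6-observer synthetic cohort analysed end to end.
mode: synthetic
synthetic:
  n_patients: 7
  n_observers: 6
  target_dsc: 0.60
thresholds:
  multipliers: [1.5, 2.0, 2.5]
  min_component_ccm: 0.1
eval_margin_mm: 20
stats:
  p_adjust: none
seed: 1
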