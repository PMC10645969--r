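# Demo experiment: all eight organ-specific contrasts on a small simulated
# cohort. Resampling is reduced (2 outer resamples, 2 inner folds) so the
# demo runs in well under a minute; raise n_resamples to 51 and k_inner to 5
# for a full-scale run.
seed: 1
output_dir: demo_results
cohort:
  group_sizes:
    brain: 6
    breast: 6
    colorectal: 6
    kidney: 6
    lung: 6
    ovarian: 6
    pancreatic: 6
    prostate: 6
    NCS: 10
  noise_sd: 0.01
  effect_amplitude: 0.05
  spectra_per_patient: 9
preprocess:
  windows: [[2700, 3700], [1000, 1800]]
  baseline: rubberband
  normalization: vector
  derivative: 0
classifier:
  family: rf
  grid:
    num_trees: [200]
    max_depth: [8]
    min_node: [5]
resampling:
  n_resamples: 2
  train_frac: 0.7
  k_inner: 2
tasks:
  - {name: brain_vs_NCS, case_groups: [brain], control_groups: [NCS],
     target_metric: sensitivity, target_minimum: 0.90}
  - {name: breast_vs_NCS, case_groups: [breast], control_groups: [NCS],
     target_metric: sensitivity, target_minimum: 0.90}
  - {name: colorectal_vs_NCS, case_groups: [colorectal], control_groups: [NCS],
     target_metric: specificity, target_minimum: 0.90}
  - {name: kidney_vs_NCS, case_groups: [kidney], control_groups: [NCS],
     target_metric: sensitivity, target_minimum: 0.90}
  - {name: lung_vs_NCS, case_groups: [lung], control_groups: [NCS],
     target_metric: sensitivity, target_minimum: 0.90}
  - {name: ovarian_vs_NCS-F, case_groups: [ovarian], control_groups: [NCS],
     sex_filter: F, target_metric: sensitivity, target_minimum: 0.90}
  - {name: pancreatic_vs_NCS, case_groups: [pancreatic], control_groups: [NCS],
     target_metric: specificity, target_minimum: 0.90}
  - {name: prostate_vs_NCS-M, case_groups: [prostate], control_groups: [NCS],
     sex_filter: M, target_metric: sensitivity, target_minimum: 0.90}
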