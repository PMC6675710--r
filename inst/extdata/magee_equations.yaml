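# New Magee equation coefficients.
# Transcribed verbatim from the public calculator at
# https://path.upmc.edu/onlineTools/mageeequations.html (accessed 2026-09-20).
# HER-2 enters each equation as a status-mapped additive term (her2_term),
# so its coefficient is fixed at 1 and the per-status values live in
# her2_term_values. ER/PR are modified H-scores (0-300), Ki-67 a percentage,
# tumor size in cm.
version: "2013-new-magee"
equations:
  eq1:
    intercept: 15.31385
    coefficients:
      nottingham_score: 1.4055
      er_h_score: -0.01924
      pr_h_score: -0.02925
      her2_term: 1.0
      tumor_size_cm: 0.78677
      ki67_pct: 0.13269
    her2_term_values:
      negative: 0.0
      equivocal: 0.77681
      positive: 11.58134
    required:
      - nottingham_score
      - er_h_score
      - pr_h_score
      - her2_term
      - tumor_size_cm
      - ki67_pct
  eq2:
    intercept: 18.8042
    coefficients:
      nottingham_score: 2.34123
      er_h_score: -0.03749
      pr_h_score: -0.03065
      her2_term: 1.0
      tumor_size_cm: 0.04267
    her2_term_values:
      negative: 0.0
      equivocal: 1.82921
      positive: 12.64016
    required:
      - nottingham_score
      - er_h_score
      - pr_h_score
      - her2_term
      - tumor_size_cm
  eq3:
    intercept: 24.30812
    coefficients:
      er_h_score: -0.02177
      pr_h_score: -0.02884
      her2_term: 1.0
      ki67_pct: 0.19455
    her2_term_values:
      negative: 0.0
      equivocal: 1.46495
      positive: 12.75525
    required:
      - er_h_score
      - pr_h_score
      - her2_term
      - ki67_pct
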