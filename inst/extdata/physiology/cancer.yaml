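# Cancer-patient physiology (scalars): reduced albumin and hematocrit,
# down-regulated hepatic CYP3A4 and CYP2C19. Brain-barrier P-gp doubling for
# crizotinib is applied by apply_cancer_physiology(), not recorded here.
population_tag: cancer
body_weight: 73
albumin_g_dl: 3.1
hematocrit: 0.33
gfr_ml_min: 120
expression:
- molecule: CYP3A4
  reference_conc_uM: 3.02
- molecule: CYP2C19
  reference_conc_uM: 0.51
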