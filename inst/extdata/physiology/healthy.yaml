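# Healthy reference physiology (scalars). Organ volumes, flows,
# sub-compartment fractions and tissue composition come from the packaged
# reference-human dataset and can be overridden programmatically.
population_tag: healthy
body_weight: 73
albumin_g_dl: 4.5
hematocrit: 0.43
gfr_ml_min: 120
expression:
- molecule: CYP3A4
  reference_conc_uM: 4.32
- molecule: CYP3A5
  reference_conc_uM: 0.04
- molecule: CYP2C8
  reference_conc_uM: 2.56
- molecule: CYP2C19
  reference_conc_uM: 0.76
- molecule: UGT1A3
  reference_conc_uM: 0.53
- molecule: UGT1A4
  reference_conc_uM: 0.25
- molecule: P-gp
  reference_conc_uM: 0.68
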