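# SYNTHETIC PLACEHOLDER perpetrator model: posaconazole.
# Literature-informed minimal disposition set with a competitive CYP3A4 Ki.
# Edit freely.
name: posaconazole
molecular_weight: 700.8
pka:
- value: 3.6
  type: base
log_p: 4.6
permeability_papp_cm_s: 4.0e-06
fup:
  healthy: 0.02
rbp:
  healthy: 0.62
gfr_fraction: 0.0
kia_scale: 1.0
kir_scale: 1.0
weibull:
  t50_min: 45.0
  shape: 1.0
k_csf_p: 0.0
pathways:
- enzyme: HLM
  cl_int: 60.0
  basis: per_mg_protein
  product: sink
transporters: []
interaction:
  ki_cyp3a4: 0.25
metabolites: []
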