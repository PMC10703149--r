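# SYNTHETIC PLACEHOLDER perpetrator model: itraconazole.
# Literature-informed minimal disposition set with a potent competitive
# CYP3A4 Ki; the hydroxy-metabolite contribution is not modelled. Edit freely.
name: itraconazole
molecular_weight: 705.6
pka:
- value: 3.7
  type: base
log_p: 5.66
permeability_papp_cm_s: 5.0e-06
fup:
  healthy: 0.002
rbp:
  healthy: 0.58
gfr_fraction: 0.0
kia_scale: 1.0
kir_scale: 1.0
weibull:
  t50_min: 60.0
  shape: 1.0
k_csf_p: 0.0
pathways:
- enzyme: HLM
  cl_int: 400.0
  basis: per_mg_protein
  product: sink
transporters: []
interaction:
  ki_cyp3a4: 0.0013
metabolites: []
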