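# SYNTHETIC PLACEHOLDER perpetrator model: ketoconazole.
# The original modulator parameter tables were not published with the ALK
# inhibitor models; this is an editable, literature-informed minimal
# disposition set carrying a potent competitive CYP3A4 Ki. Edit freely.
name: ketoconazole
molecular_weight: 531.4
pka:
- value: 6.5
  type: base
- value: 2.9
  type: base
log_p: 4.35
permeability_papp_cm_s: 9.0e-06
fup:
  healthy: 0.029
rbp:
  healthy: 0.62
gfr_fraction: 0.0
kia_scale: 1.0
kir_scale: 1.0
weibull:
  t50_min: 20.0
  shape: 1.0
k_csf_p: 0.0
pathways:
- enzyme: HLM
  cl_int: 120.0
  basis: per_mg_protein
  product: sink
transporters: []
interaction:
  ki_cyp3a4: 0.015
metabolites: []
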