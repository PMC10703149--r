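# SYNTHETIC PLACEHOLDER perpetrator model: rifampin (rifampicin).
# Literature-informed minimal disposition set with CYP3A4 induction
# (Emax/EC50 on unbound hepatic concentration) and a weak competitive Ki.
# Auto-induction of rifampin clearance is not modelled. Edit freely.
name: rifampin
molecular_weight: 822.9
pka: []
log_p: 2.7
permeability_papp_cm_s: 1.5e-05
fup:
  healthy: 0.2
rbp:
  healthy: 0.9
gfr_fraction: 0.1
kia_scale: 1.0
kir_scale: 1.0
weibull:
  t50_min: 30.0
  shape: 1.0
k_csf_p: 0.0
pathways:
- enzyme: HLM
  cl_int: 12.0
  basis: per_mg_protein
  product: sink
transporters: []
interaction:
  ki_cyp3a4: 18.5
  emax_cyp3a4: 12.0
  ec50_cyp3a4: 0.32
metabolites: []
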