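# SYNTHETIC PLACEHOLDER victim probe: midazolam (generic CYP3A4 substrate).
# Literature-informed minimal disposition set; near-complete CYP3A4-mediated
# clearance so that modulator effects read out directly. Edit freely.
name: midazolam
molecular_weight: 325.8
pka:
- value: 6.2
  type: base
log_p: 3.53
permeability_papp_cm_s: 3.0e-05
fup:
  healthy: 0.03
rbp:
  healthy: 0.66
gfr_fraction: 0.0
kia_scale: 1.0
kir_scale: 1.0
weibull:
  t50_min: 10.0
  shape: 1.2
k_csf_p: 0.0
pathways:
- enzyme: CYP3A4
  cl_int: 300.0
  basis: per_mg_protein
  product: sink
transporters: []
metabolites: []
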