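# Alectinib metabolite M4 (active). Formed from the alectinib CYP3A4 pathway;
# full whole-body disposition with its own binding and clearance parameters.
# Permeability is assigned from the parent (not separately measured).
name: alectinib-m4
molecular_weight: 456.6
pka:
- value: 7.35
  type: base
log_p: 4.69           # assigned
permeability_papp_cm_s: 1.88e-06   # assigned from parent
fup:
  healthy: 0.006
  patient: 0.009
rbp:
  healthy: 2.5
  patient: 2.8
gfr_fraction: 1.0
kia_scale: 0.5
kir_scale: 0.5
weibull:
  t50_min: 60.0       # unused (not orally dosed)
  shape: 0.92
k_csf_p: 0.79         # assigned from parent
k_csf_reference: unbound_plasma
cl_additional_l_h_kg: 0.42
pathways:
- enzyme: CYP3A4
  cl_int: 1.71        # uL/min/pmol enzyme; converting to M6
  basis: per_pmol_enzyme
  product: sink
- enzyme: HLM
  cl_int: 1330.0
  basis: per_mg_protein
  product: sink
transporters: []
interaction:
  ki_cyp3a4: 7.0
  kinact_cyp3a4: 3.7
metabolites: []
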