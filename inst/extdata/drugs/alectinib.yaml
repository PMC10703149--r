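# Alectinib (ALE) PBPK input parameters. The CYP3A4 pathway forms the active
# metabolite M4 (see alectinib-m4.yaml); the unspecified HLM clearance is a
# non-inducible, non-inhibitable hepatic intrinsic clearance.
name: alectinib
molecular_weight: 482.6
pka:
- value: 7.2
  type: base
log_p: 4.69
solubility_mg_ml: 0.023
permeability_papp_cm_s: 1.88e-06
fup:
  healthy: 0.003
  patient: 0.004
rbp:
  healthy: 2.6
  patient: 3.0
gfr_fraction: 1.0
kia_scale: 2.0
kir_scale: 2.0
weibull:
  t50_min: 60.0
  shape: 0.92
k_csf_p: 0.79
k_csf_reference: unbound_plasma
cl_additional_l_h_kg: 0.28
pathways:
- enzyme: CYP3A4
  cl_int: 9.98        # uL/min/pmol enzyme
  basis: per_pmol_enzyme
  product: alectinib-m4
- enzyme: HLM
  cl_int: 1710.0      # uL/min/mg microsomal protein
  basis: per_mg_protein
  product: sink
transporters: []
interaction:
  ki_cyp3a4: 8.3
  kinact_cyp3a4: 3.7
  emax_cyp3a4: 3.5
  ec50_cyp3a4: 1.0
metabolites:
- alectinib-m4
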