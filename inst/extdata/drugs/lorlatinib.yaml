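# Lorlatinib (LOR) PBPK input parameters. The recombinant-enzyme velocities
# were scaled with intersystem extrapolation factors (ISEF) and enzyme
# abundances to the per-mg-microsomal-protein intrinsic clearances recorded
# here; metabolite M8 is a formation sink.
name: lorlatinib
molecular_weight: 406.4
pka:
- value: 4.9
  type: base
log_p: 2.47
solubility_mg_ml: 0.11
permeability_papp_cm_s: 2.8e-05
fup:
  healthy: 0.34
  patient: 0.43
rbp:
  healthy: 0.99
  patient: 1.1
gfr_fraction: 1.0
kia_scale: 3.0
kir_scale: 1.0
weibull:
  t50_min: 30.0
  shape: 0.92
k_csf_p: 0.77
k_csf_reference: unbound_plasma
pathways:
- enzyme: CYP3A4
  v_max: 3.10         # pmol/min/mg microsomal protein
  k_m: 2.12           # uM
  product: sink       # M6/M8 formation sink
- enzyme: CYP3A4
  cl_int: 0.042       # uL/min/mg, M2a route
  basis: per_mg_protein
  product: sink
- enzyme: CYP3A5
  cl_int: 0.11
  basis: per_mg_protein
  product: sink
- enzyme: CYP2C8
  cl_int: 0.20
  basis: per_mg_protein
  product: sink
- enzyme: CYP2C19
  cl_int: 0.05
  basis: per_mg_protein
  product: sink
- enzyme: UGT1A3
  cl_int: 0.012       # uL/min/mg, M1a route
  basis: per_mg_protein
  product: sink
- enzyme: UGT1A4
  cl_int: 0.10
  basis: per_mg_protein
  product: sink
transporters: []
interaction:
  ki_cyp3a4: 328.2
  emax_cyp3a4: 5.99
  ec50_cyp3a4: 0.29
metabolites: []
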