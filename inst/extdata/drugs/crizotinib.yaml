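# Crizotinib (CRI) PBPK input parameters.
# Patient (cancer) values of fup/Rbp are derived from the albumin/hematocrit
# scaling equations; the values recorded here are the tabulated ones.
name: crizotinib
molecular_weight: 450.3
pka:
- value: 9.4
  type: base
- value: 5.6
  type: base
log_p: 4.28
solubility_mg_ml: 0.74
permeability_papp_cm_s: 1.6e-05
fup:
  healthy: 0.093
  patient: 0.13
rbp:
  healthy: 1.1
  patient: 1.2
gfr_fraction: 1.0
kia_scale: 5.0
kir_scale: 1.0
weibull:
  t50_min: 45.0
  shape: 0.92
k_csf_p: 0.0026
k_csf_reference: total_plasma
pathways:
- enzyme: CYP3A4
  cl_int: 103.0       # uL/min/mg microsomal protein
  basis: per_mg_protein
  product: sink       # PF-06260182 disposition out of scope
transporters:
- transporter: P-gp
  cl_int: 1.49        # uL/min/10^6 cells; an alternative estimate of 1.9
                      # from transfected-cell Peff data exists, the
                      # tabulated 1.49 is shipped
  k_m: 8.5            # uM
  site: brain
interaction:
  ki_cyp3a4: 1.9      # uM, half-maximal inactivation concentration
  kinact_cyp3a4: 6.6  # 1/h
  emax_cyp3a4: 10.4
  ec50_cyp3a4: 0.24   # uM
  ki_pgp: 7.8         # uM, carried but not used in shipped simulations
metabolites: []
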