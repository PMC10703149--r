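# alkpbpk

Whole-body physiologically based pharmacokinetic (PBPK) simulation of the
ALK inhibitors **crizotinib**, **alectinib** (with its active metabolite M4)
and **lorlatinib**, for the question that drives their clinical use in
ALK-positive non-small-cell lung cancer: does a dosing regimen keep enough
unbound drug in plasma — and in cerebrospinal fluid, where brain metastases
live — to occupy the ALK kinase, including its resistance mutants?

The package is aimed at PK modellers and DMPK scientists. It provides:

- a 12-organ PBPK engine (deSolve) with permeability-limited tissues,
  Rodgers–Rowland tissue partitioning, Weibull-dissolution oral absorption,
  expression-scaled hepatic metabolism, P-gp efflux at the blood–brain
  barrier, and renal filtration `CL_R = GFR · f_up · f_renal`;
- a hepatic CYP3A4 turnover model for time-dependent inhibition and
  induction (`dE/dt = k_deg E_0 (1 + E_max I/(EC50+I)) − k_deg E −
  k_inact I/(K_I+I) E`), used both for auto-interaction and victim–
  perpetrator co-simulation (`co_simulate()`);
- disease-state scaling for cancer patients: albumin-driven unbound
  fraction `f'_up = 1/(1 + (1−f_up)/f_up · [P]'/[P])`, hematocrit-driven
  blood-to-plasma ratio via the blood-cell affinity
  `K_puBC = (Hct − 1 + R_bp)/(Hct · f_up)`, down-regulated hepatic CYP3A4
  and CYP2C19, doubled brain P-gp for crizotinib;
- CSF mapping `C_CSF = C_p · f'_up · K_CSF,P` (with per-drug provenance of
  the ratio) and equilibrium ALK occupancy
  `AO = 100 · I_free/(K_i + I_free)` on wild-type, L1196M, G1269A and
  G1202R;
- virtual populations with geometric-mean / CV% / log-normal-CI summaries,
  local sensitivity analysis (±20% sensitivity coefficients), a brain P-gp
  expression scan, and a synthetic "observed data" generator with the
  0.5–2.0 fold-error accuracy window.

All drug and physiology inputs ship as editable YAML configs
(`alk_config()`); perpetrator models (ketoconazole, itraconazole,
posaconazole, rifampin, midazolam) are literature-informed placeholder
configs marked as such.

## Worked example

Steady-state crizotinib 250 mg BID in a cancer patient, with occupancy
against the four ALK variants:

```r
library(alkpbpk)

drugs <- load_drug_set("crizotinib")
cp    <- apply_cancer_physiology(default_human_physiology(), drugs[[1]])
drugs[[1]] <- cp$drug

model <- build_model(drugs, cp$physiology)
ss <- simulate_steady_state(model, regimen("oral", 250, interval_h = 12),
                            simulation_settings(rtol = 1e-6, atol = 1e-8))
ss$metrics
#> <pk_metrics> crizotinib / plasma_total_ngml
#>   AUC 2696 conc*h, Cmax 281.4, Ctrough 178.3

assess_regimen(rep(ss$metrics$ctrough, 10), drugs[[1]],
               read_alk_variants("crizotinib"))
#> <regimen_assessment> gm total plasma Ctrough 178.3 ng/mL; AO threshold 75 %
#>      variant ki_nM   site ctrough_unbound_nM min_ao_pct ... pass
#> 1  wild-type    10 plasma              51.30     83.688 ... FALSE
#> 2  wild-type    10    csf               1.03      9.335 ... FALSE
#> 3     L1196M   446 plasma              51.30     10.317 ... FALSE
#> ...
```

The simulated trough (178 ng/mL total plasma) sits within two-fold of the
clinically reported 259 ng/mL; the unbound plasma trough gives ~84%
wild-type occupancy (threshold 75%) while the CSF trough does not — the
model's restatement of why crizotinib controls systemic but not intracranial
disease. With the tabulated clinical trough the wild-type plasma occupancy
is 88.7% and the intracranial one 13.5%.

A drug–drug interaction run:

```r
lib  <- ddi_design_library("cri_ketoconazole")
perp <- read_drug_config(alk_config("perpetrators", lib$perpetrator_config))
co_simulate(load_drug_set("crizotinib"), perp, default_human_physiology(),
            lib$design, simulation_settings(rtol = 1e-6, atol = 1e-8))
#> <ddi_result> crizotinib + ketoconazole
#>   AUC ratio 2.48, Cmax ratio 1.46
```

(clinically observed AUC ratio: 3.16 — inside the two-fold accuracy window
the field uses for DDI predictions).

A command-line wrapper over the same pipeline lives in
`inst/scripts/alkpbpk.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/alkpbpk.R", package="alkpbpk"))')" \
    occupancy --out out/ --drug crizotinib --population cancer --seed 1
```

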