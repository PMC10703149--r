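---
title: "Whole-body PBPK models of crizotinib, alectinib and lorlatinib: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-body PBPK models of crizotinib, alectinib and lorlatinib: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(alkpbpk)
```

This vignette documents the science implemented in `alkpbpk`: the model
equations, the parameters that matter and their defaults, the numerical
choices, and the limits of what the shipped simulations can claim. It is the
package's record of *why* the model looks the way it does; the README shows
*how* to run it.

## The problem

ALK-rearranged non-small-cell lung cancer frequently metastasises to the
brain, so the clinical question for an ALK inhibitor is twofold: does the
dosing regimen maintain enough unbound drug in plasma, and does enough of it
reach the cerebrospinal fluid (CSF) to engage the kinase behind the
blood-brain barrier - including resistance variants (L1196M, G1269A, G1202R)
with weaker binding? The package answers both with whole-body physiologically
based pharmacokinetic (PBPK) models for crizotinib (CRI), alectinib (ALE,
with its active metabolite M4) and lorlatinib (LOR), coupled to an
equilibrium target-occupancy model.

## Model structure

Twelve tissues (lung, brain, heart, kidney, liver, gut, spleen, muscle,
adipose, skin, bone, rest) are connected by blood flow through arterial and
venous pools; gut and spleen drain through the portal vein into the liver.
Each tissue carries three dynamic sub-compartments - vascular, interstitial,
intracellular - with plasma and blood cells taken to be in instantaneous
equilibrium within the vascular space through the blood-to-plasma ratio
(R~bp~), so the four anatomical sub-compartments are represented with three
states per organ.

Exchange is written in unbound-concentration potentials, which makes the
fluxes thermodynamically consistent by construction:

- vascular to interstitial: `PS_vas * (fup * C_blood / Rbp - C_int / K_int)`,
- interstitial to intracellular: `PS_cell * (C_int / K_int - C_cell / K_cell)`.

`K_int` and `K_cell` are equilibrium partition coefficients relative to
unbound plasma, from the Rodgers-Rowland tissue-composition scheme: strong
bases (basic pKa >= 7: CRI, ALE, M4) associate with acidic phospholipids,
with the association constant back-calculated from the measured blood-cell
partition (K~puBC~, itself derived from R~bp~, f~up~ and hematocrit); weak
bases and neutrals (LOR) bind extracellular protein scaled from 1/f~up~.
Intracellular coefficients are multiplied by the drug-specific `kia_scale`
(5.0 CRI, 2.0 ALE, 0.5 M4, 3.0 LOR) and interstitial ones by `kir_scale`,
the optimized partition multipliers of the source models. Ion trapping of
bases at intracellular pH 7.0 versus plasma 7.4 enters both the equilibrium
coefficients and the unbound intracellular concentration that drives
metabolism and enzyme interactions.

### Absorption

Oral doses dissolve in the gut lumen by a Weibull profile anchored so that
half the dose is dissolved at the tabulated "Weibull time"
(`F(t) = 1 - exp(-ln 2 (t/t50)^shape)`; t50 = 45/60/30 min and shape 0.92).
Dissolved drug is absorbed into the portal circulation with a first-order
rate constant `ka = 2 Peff / r`, where the human jejunal effective
permeability Peff comes from the standard log-log correlation with monolayer
Papp (slope 0.4926, intercept -0.1454 on the 1e-6 / 1e-4 cm/s scales) and
r = 1.25 cm. Undissolved and dissolved material leaves the absorbing segment
with a 3.25 h mean transit time. This reproduces sensible absorbed fractions
(~0.85 CRI, ~0.65 ALE, ~0.88 LOR) without a compartmental transit chain;
enterohepatic recirculation and regional solubility limits are out of scope.

### Clearance

Hepatic intrinsic clearances are scaled to the whole liver with
45 mg microsomal protein per g liver and the packaged liver size (1800 g /
1.65 L), and by enzyme expression relative to the tabulated liver reference
concentrations (CYP3A4 4.32 uM/L liver, CYP3A5 0.04, CYP2C8 2.56, CYP2C19
0.76, UGT1A3 0.53, UGT1A4 0.25; P-gp 0.68). Per-pmol-enzyme clearances scale
with `60 * E * V_liver`; Michaelis-Menten pathways (LOR CYP3A4) saturate on
the unbound intracellular concentration. The "unspecified HLM" clearances of
ALE and M4 are non-inducible, non-inhibitable first-order hepatic processes.
Renal clearance is `GFR * fup * gfr_fraction`; ALE and M4 additionally carry
the tabulated plasma clearances (0.28 and 0.42 L/h/kg). The recombinant
velocities behind the tabulated LOR pathway clearances were already
ISEF-scaled to a per-mg-microsomal-protein basis
(`isef_scaled_clint()` exposes the scaling rule; defaults 0.21 CYP3A4, 0.12
CYP3A5, 1.41 CYP2C8, 0.25 CYP2C19, 0.077 UGT1A3/1A4); reading them as
per-pmol velocities instead would make CYP2C8 dominate lorlatinib clearance,
contradicting its known CYP3A4-dominant elimination.

### Enzyme turnover and interactions

Hepatic CYP3A4 is a dynamic pool with 36 h turnover half-life:

```
dE/dt = kdeg (1 + sum Emax_j I_j / (EC50_j + I_j))      # induced synthesis
        - kdeg E                                        # degradation
        - s * sum kinact_j I_j / (KI_j + I_j) * E       # inactivation
```

driven by each perpetrator's unbound liver intracellular concentration
(configurable to venous plasma). Reversible inhibition scales CYP3A4 flux of
a victim by `1/(1 + sum_{j != victim} I_j / Ki_j)`. CRI and ALE act on their
own metabolism through both inactivation and induction (auto-interaction);
LOR through induction only, which reproduces the clinically observed rise in
its clearance on repeated dosing.

The factor `s` (`mbi_scale`, default 0.35) attenuates the in-vitro
inactivation kinetics in vivo. Applied at face value, the tabulated
crizotinib kinact/K~I~ (6.6 h^-1 / 1.9 uM) makes auto-inactivation outrun
the optimized auto-induction at any clinically realistic concentration and
the predicted steady-state exposure runs away to many-fold above every
published observation - including the source model's own predictions, which
cannot have used the unattenuated term with this turnover model. In-vivo
attenuation of microsome-derived mechanism-based-inactivation potency is
standard PBPK practice; the value 0.35 was calibrated once against the
clinical steady-state exposure of crizotinib (250 mg BID patients) during
model development and is not a per-simulation tuning knob.

### Blood-brain barrier and CSF

The brain vascular-interstitial exchange surface carries a tightness factor
(2e-4) representing the barrier; P-gp pumps drug from brain interstitial
back to plasma with Michaelis-Menten kinetics (CRI: CLint 1.49 uL/min/10^6
cells, K~m~ 8.5 uM), with capacity proportional to the barrier P-gp
concentration (liver reference 0.68 uM x brain relative expression 1.25;
doubled in CRI patients). The proportionality constant (5.6e4 10^6-cell
units per uM) was fixed so the healthy model reproduces the observed
CSF-to-plasma ratio of crizotinib (~0.0026 on total plasma); with it, the
unbound brain interstitial trough sits ~50-fold below unbound plasma.

Reported CSF concentrations use the ratio mapping
`C_CSF = C_p * fup' * K_CSF,P`, with a provenance flag per drug because the
literature ratios are heterogeneous: ALE (0.79) and LOR (0.77) are
referenced to unbound plasma (the formula above), while the CRI ratio
(0.0026) already relates CSF to *total* plasma, so the unbound fraction must
not be applied twice. Both conventions reproduce their printed anchors
(LOR 160 nM x 0.77 = 123 nM; CRI 78.2/0.13 nM total x 0.0026 = 1.56 nM).

### Occupancy and regimen assessment

Equilibrium ALK occupancy is `AO = 100 I_free / (Ki + I_free)` with variant
K~i~ values from kinase IC50s at the ATP K~m~ (Cheng-Prusoff halving).
Because occupancy is monotone in concentration, the minimal occupancy over a
dosing interval is the occupancy at trough. A regimen passes for a variant
when the geometric-mean total plasma trough meets the tabulated threshold
(235 ng/mL CRI, 435 ALE; 7.6/62/150 ng/mL for LOR wild-type/L1196M/G1202R -
the L1196M threshold is also reported as 622 in the same source's
discussion; the tabulated 62 is shipped) and mean occupancy exceeds 75%.
Occupancy for "ALE + M4" uses the ALE unbound trough alone, which reproduces
the tabulated values; a potency-weighted sum with M4 can be formed manually
from the M4 profile.

### Disease state

The cancer-patient switch changes exactly five things: hepatic CYP3A4
expression 4.32 to 3.02 uM/L, CYP2C19 0.76 to 0.51, albumin 4.5 to 3.1 g/dl,
hematocrit 0.43 to 0.33, and (CRI only) doubled brain-barrier P-gp. Patient
unbound fractions follow the albumin-scaling equation and patient
blood-to-plasma ratios follow from the invariant blood-cell affinity with
the patient hematocrit; the printed table rounds these (0.093 to 0.13,
0.003 to 0.004, 0.34 to 0.43; R~bp~ 1.1 to 1.2 and 0.99 to 1.1). The
tabulated ALE patient R~bp~ of 3.0 is not reproducible from the equations
(they give 2.93, rounding to 2.9); the shipped config records the tabulated
3.0 and the engine derives the unrounded value, and that cell is excluded
from exact comparisons. Where prose and table conflict (e.g. a "45%" CYP3A4
reduction versus 4.32 to 3.02), the table concentrations win.

## Virtual populations

Subjects are drawn with uniform age in range (default 30-70 y), a stated
female proportion (default 50%), sex-specific log-normal weight; cohorts
smaller than 10 are padded to 10, as in the source protocol. Organ volumes
scale linearly and flows/GFR with the 3/4 power of weight. The source does
not state inter-individual variability magnitudes; defaults of 30% CV on
enzyme/transporter expression and 20% on flows (log-normal, configurable)
produce plasma exposure CVs in the 30-60% range typical of the clinical
tables. Summaries are geometric means with log-scale CV% and log-normal
quantile confidence intervals (90% default for tables, 95% available),
matching geometric-mean reporting; no bootstrap. With the variability CVs
set to zero the sampled physiologies reduce to the allometrically scaled
base individual.

## Synthetic observed data

`synthesize_observed()` emulates the statistical shape of the clinical
comparison tables: sparse nominal sampling times, per-subject multiplicative
log-normal residual error at a stated CV%, and geometric-mean/CV% summaries,
seeded and reproducible. It deliberately does not emulate real-data features
such as below-quantification censoring, dropout, dosing-history errors or
assay bias - so tests built on it demonstrate statistical round-trip
correctness of the pipeline, not robustness to messy clinical data.
`prediction_observation_ratio()` applies the standard 0.5-2.0 fold-error
accuracy window.

## Numerical choices

- Stiff integration (lsoda), rtol 1e-8 / atol 1e-10 defaults; dosing as
  solver events. Development checks use 1e-6/1e-8 where 0.1%-level accuracy
  is not being asserted.
- Permeability-surface products are capped at 500x the organ blood flow
  (`ps_cap_factor`): exchange faster than that is indistinguishable from
  flow-limited at the reporting timescale and only adds stiffness.
  Kidney, liver, spleen and gut mucosa carry larger exchange surfaces than
  continuous-capillary organs (fenestrated/sinusoidal endothelium); without
  this the liver is uptake-limited for permeable drugs and oral exposure
  stops responding to enzyme induction, contradicting the observed
  rifampin interactions.
- The Weibull dissolution hazard is capped at 100/h (the shape 0.92 hazard
  is weakly singular at the dose time; the cap bounds the step size without
  measurably changing the dissolved fraction).
- Steady state is operationalized as: at least 14 simulated days, extended
  in 7-day blocks (cap 35) until successive-interval troughs agree within
  1%. BID = every 12 h, OD = every 24 h, first dose at t = 0.
- Mass balance (dose + formed = present + eliminated + lumen losses) holds
  to <1e-6 relative in the shipped tests; state non-negativity to solver
  noise.
- Problem sizes in the test suite: closed-form reductions over 3-4 days;
  patient steady states 14-28 days; the brain P-gp scan 21 days (the
  zero-efflux brain fills slowly through the tight barrier, so shorter
  spans understate the efflux-absent fold change); population checks with
  3-10 subjects and the statistical recovery checks with n = 500 synthetic
  subjects.

## Known limitations

- Alectinib's hepatic uptake is permeability-limited in this engine (very
  low Papp and f~up~), so much of its clearance routes through the tabulated
  additional plasma clearance and its predicted CYP3A4 interaction ratios
  are muted (~1.0 versus observed 1.75 with posaconazole). The crizotinib
  interaction designs, which the engine does capture (ketoconazole ~2.5 vs
  observed 3.16; rifampin ~0.33 vs 0.18), are the ones used for
  calibration-level checks.
- Predicted absolute Cmax values are less reliable than troughs and AUC
  (single-pathway absorption model); comparisons are two-fold-level, never
  exact.
- The perpetrator parameter sets are literature-informed placeholders (the
  source supplement is unavailable); they are shipped as editable configs
  marked as synthetic stand-ins.
- The tabulated UGT1A3/1A4 reference concentrations (0.53/0.25 uM) do not
  follow from the stated abundances under any consistent organ-size choice;
  the tabulated values are shipped as-is and the abundance conversion
  remains available as a utility (`ugt_reference_concentration()`).
- Lorlatinib occupancy rows in the source table are not algebraically
  consistent with their own printed trough and K~i~ inputs (e.g. L1196M:
  equation gives ~90.4%, table prints 93.8%); they are excluded from exact
  checks.
- Unbound brain interstitial fluid is used as the CSF surrogate for the
  P-gp analysis; real CSF turnover, bulk flow and choroid plexus transport
  are not modelled.
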