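# ALK variant binding constants (Ki, nM) per inhibitor and the
# efficacy-linked plasma trough thresholds (total plasma, ng/mL).
# Ki values derive from kinase-assay IC50s at the ATP Km level
# (Cheng-Prusoff halving). The occupancy threshold is 75% for all drugs.
# The lorlatinib L1196M threshold is recorded as 62 ng/mL; a value of 622
# also appears in the source literature for the same quantity.
crizotinib:
  ao_threshold_pct: 75
  variants:
  - name: wild-type
    ki_nM: 10.0
    ctrough_threshold_ngml: 235.0
  - name: L1196M
    ki_nM: 446.0
  - name: G1269A
    ki_nM: 250.0
  - name: G1202R
    ki_nM: 191.0
alectinib:
  ao_threshold_pct: 75
  variants:
  - name: wild-type
    ki_nM: 1.0
    ctrough_threshold_ngml: 435.0
  - name: L1196M
    ki_nM: 0.8
  - name: G1269A
    ki_nM: 4.0
  - name: G1202R
    ki_nM: 29.0
lorlatinib:
  ao_threshold_pct: 75
  variants:
  - name: wild-type
    ki_nM: 1.0
    ctrough_threshold_ngml: 7.6
  - name: L1196M
    ki_nM: 17.0
    ctrough_threshold_ngml: 62.0
  - name: G1269A
    ki_nM: 5.0
  - name: G1202R
    ki_nM: 25.0
    ctrough_threshold_ngml: 150.0
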