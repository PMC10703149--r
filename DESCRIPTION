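Package: alkpbpk
Title: Physiologically Based Pharmacokinetic Simulation of ALK Inhibitors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Whole-body physiologically based pharmacokinetic (PBPK) models for the
    anaplastic lymphoma kinase (ALK) inhibitors crizotinib, alectinib (with its active
    metabolite M4) and lorlatinib. Simulates plasma and cerebrospinal-fluid exposure in
    healthy subjects and cancer patients, CYP3A4-mediated drug-drug interactions through
    enzyme turnover (mechanism-based inactivation and induction), P-glycoprotein efflux
    at the blood-brain barrier, equilibrium ALK occupancy on wild-type and mutant
    kinases, virtual-population summaries, local sensitivity analysis, and assessment of
    dosing regimens against trough-concentration and occupancy thresholds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
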