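test_that("albumin scaling of the unbound fraction matches tabulated patient values", {
  expect_equal(round_half_up(scale_fup_to_patient(0.093, 4.5, 3.1), 2), 0.13)
  expect_equal(round_half_up(scale_fup_to_patient(0.003, 4.5, 3.1), 3), 0.004)
  expect_equal(round_half_up(scale_fup_to_patient(0.34, 4.5, 3.1), 2), 0.43)
  # fully unbound drug and unchanged albumin are identities
  expect_equal(scale_fup_to_patient(1, 4.5, 3.1), 1)
  expect_equal(scale_fup_to_patient(0.34, 4.5, 4.5), 0.34)
  expect_error(scale_fup_to_patient(0, 4.5, 3.1))
  expect_error(scale_fup_to_patient(0.1, -1, 3.1))
})

test_that("unbound fraction scaling is monotone and maps (0,1] into (0,1]", {
  fups <- c(0.001, 0.01, 0.093, 0.3, 0.9, 1)
  albs <- c(4.5, 4.0, 3.1, 2.0)
  for (f in fups) {
    prev <- f
    for (a in albs[-1]) {
      val <- scale_fup_to_patient(f, 4.5, a)
      expect_gt(val, 0)
      expect_lte(val, 1)
      if (f < 1) expect_gt(val, prev) else expect_equal(val, 1)
      prev <- val
    }
  }
})

test_that("blood-cell affinity and patient Rbp reproduce tabulated values", {
  expect_equal(compute_kpu_bc(0.093, 1.1, 0.43), 13.25, tolerance = 0.01 / 13.25)
  expect_equal(compute_kpu_bc(1, 1, 0.43), 1)
  expect_equal(compute_kpu_bc(0.003, 2.6, 0.43), 1573.6, tolerance = 0.5 / 1573.6)
  expect_error(compute_kpu_bc(0.5, 0.2, 0.43), "blood-cell exclusion")

  expect_equal(round_half_up(
    scale_rbp_to_patient(0.12956, 13.253, 0.33), 1), 1.2)
  expect_equal(round_half_up(
    scale_rbp_to_patient(0.4278, 2.8728, 0.33), 1), 1.1)
  # bracket vanishes when fup' * KpuBC = 1
  expect_equal(scale_rbp_to_patient(0.25, 4, 0.33), 1)
})

test_that("Kpu_BC / Rbp round-trip is the algebraic identity at healthy values", {
  grid <- expand.grid(fup = c(0.003, 0.093, 0.34, 0.9),
                      rbp = c(0.8, 0.99, 1.1, 2.6), hct = c(0.33, 0.43))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    if (g$hct - 1 + g$rbp < 0) next
    k <- compute_kpu_bc(g$fup, g$rbp, g$hct)
    expect_equal(scale_rbp_to_patient(g$fup, k, g$hct), g$rbp,
                 tolerance = 1e-9)
  }
})

test_that("Cheng-Prusoff correction halves at the Km substrate level", {
  expect_equal(cheng_prusoff_ki(20, 1), 10)
  expect_equal(cheng_prusoff_ki(20, 0), 20)
  expect_equal(cheng_prusoff_ki(58, 1), 29)
  for (ic50 in c(0.1, 1, 17, 446)) {
    expect_identical(cheng_prusoff_ki(ic50, 1), ic50 / 2)
  }
})

test_that("ISEF scaling multiplies velocities and defaults by enzyme", {
  expect_equal(isef_scaled_clint(10, 0.21), 2.1)
  expect_equal(isef_scaled_clint(0, 5), 0)
  expect_equal(isef_scaled_clint(5, enzyme = "CYP2C8"), 7.05)
  expect_equal(isef_scaled_clint(1, enzyme = "UGT1A3"), 0.077)
  expect_error(isef_scaled_clint(1, enzyme = "CYP1A2"), "no default ISEF")
})

test_that("liver reference concentrations follow the abundance conversions", {
  expect_equal(ugt_reference_concentration(15.3, 45, 1800, 1.7), 0.729,
               tolerance = 0.001 / 0.729)
  expect_equal(ugt_reference_concentration(0, 45, 1800, 1.7), 0)
  expect_equal(ugt_reference_concentration(44.3, 45, 1800, 1.7), 2.111,
               tolerance = 0.001 / 2.111)
  expect_equal(round_half_up(
    pgp_reference_concentration(1.60, 1252, 0.56, 1.65), 2), 0.68)
  expect_equal(pgp_reference_concentration(0), 0)
  expect_equal(pgp_reference_concentration(1.0, 1000, 0.5, 1.0), 0.5)
})

test_that("parameter constructors reject out-of-range fields", {
  expect_error(drug_parameters(name = "x", molecular_weight = -1, log_p = 1,
                               permeability_papp = 1e-6, fup_healthy = 0.1,
                               rbp_healthy = 1))
  expect_error(drug_parameters(name = "x", molecular_weight = 400, log_p = 1,
                               permeability_papp = 1e-6, fup_healthy = 1.2,
                               rbp_healthy = 1))
  expect_error(drug_parameters(name = "x", molecular_weight = 400, log_p = 1,
                               permeability_papp = 1e-6, fup_healthy = 0.5,
                               rbp_healthy = 1, weibull_t50 = 0))
  expect_error(enzyme_pathway("CYP3A4"))
  expect_error(enzyme_pathway("CYP3A4", cl_int = 1, v_max = 1, k_m = 1))
  expect_error(enzyme_pathway("CYP3A4", v_max = -1, k_m = 1))
  expect_error(interaction_parameters(kinact_cyp3a4 = 6.6))
  expect_error(transporter_process(cl_int = 0, k_m = 8.5))
  expect_error(alk_variant("wild-type", ki = 0))
})

test_that("shipped drug configs round-trip through write/read without loss", {
  for (nm in c("crizotinib", "alectinib", "alectinib-m4", "lorlatinib")) {
    d <- read_drug_config(alk_config("drugs", paste0(nm, ".yaml")))
    tmp <- tempfile(fileext = ".yaml")
    write_drug_config(d, tmp)
    d2 <- read_drug_config(tmp)
    expect_equal(d2, d, info = nm)
    unlink(tmp)
  }
})

test_that("cancer physiology switch applies the tabulated adjustments", {
  cri <- read_drug_config(alk_config("drugs", "crizotinib.yaml"))
  ale <- read_drug_config(alk_config("drugs", "alectinib.yaml"))
  healthy <- default_human_physiology()
  cp <- apply_cancer_physiology(healthy, cri)
  et <- cp$physiology$expression_table
  expect_equal(et$reference_conc_uM[et$molecule == "CYP3A4"], 3.02,
               tolerance = 1e-9)
  expect_equal(et$reference_conc_uM[et$molecule == "CYP2C19"], 0.51,
               tolerance = 1e-9)
  expect_equal(cp$physiology$albumin, 3.1)
  expect_equal(cp$physiology$hematocrit, 0.33)
  # brain-barrier P-gp doubled for crizotinib only
  base_rel <- healthy$expression_table$rel_brain[
    healthy$expression_table$molecule == "P-gp"]
  expect_equal(et$rel_brain[et$molecule == "P-gp"], 2 * base_rel)
  cp_ale <- apply_cancer_physiology(healthy, ale)
  expect_equal(cp_ale$physiology$expression_table$rel_brain[
    et$molecule == "P-gp"], base_rel)
  # derived patient binding matches the tabulated rounded values
  expect_equal(round_half_up(cp$drug$fup_patient, 2), 0.13)
  expect_equal(round_half_up(cp_ale$drug$fup_patient, 3), 0.004)
  expect_equal(round_half_up(cp$drug$rbp_patient, 1), 1.2)
  expect_error(apply_cancer_physiology(cp$physiology, cri), "already")
})
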