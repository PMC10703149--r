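test_that("sensitivity coefficient arithmetic", {
  expect_equal(sensitivity_coefficient(100, 110, 1.0, 1.2), 0.5)
  expect_equal(sensitivity_coefficient(100, 100, 1.0, 1.2), 0)
  # strict proportionality gives SC = 1 for any perturbation
  for (f in c(0.8, 1.2, 1.5)) {
    expect_equal(sensitivity_coefficient(50, 50 * f, 2, 2 * f), 1)
  }
  expect_error(sensitivity_coefficient(0, 1, 1, 2), "zero baseline")
  expect_error(sensitivity_coefficient(1, 2, 1, 1))
})

test_that("clearance sensitivity in the linear limit matches the closed form", {
  # AUC = F D / CL: discrete +/-20% coefficients equal the analytic
  # finite-difference values of 1/CL
  victim <- probe_drug("victim", cl_plasma_lph = 0, papp = 3e-5)
  victim$pathways <- list(enzyme_pathway("CYP3A4", cl_int = 2,
                                         cl_int_basis = "per_mg_protein"))
  phys <- mixing_physiology(200)
  # metrics are taken over the final dosing interval at steady state,
  # where AUC_tau = F D / CL
  sc <- local_scan(victim, phys, regimen("oral", 10, 24, 5),
                   panel = "expression_CYP3A4",
                   settings = simulation_settings(t_end_h = 120,
                                                  rtol = 1e-7, atol = 1e-9))
  auc <- sc[sc$output == "AUC", ]
  expect_equal(auc$sc_up, (1 / 1.2 - 1) / 0.2, tolerance = 0.02)
  expect_equal(auc$sc_down, (1 / 0.8 - 1) / -0.2, tolerance = 0.02)
  expect_lt(abs(auc$sc_central - mean(c(auc$sc_up, auc$sc_down))), 1e-12)
  # up and down coefficients agree in sign for this monotone output
  expect_equal(sign(auc$sc_up), sign(auc$sc_down))
})

test_that("a parameter with no engaged pathway has zero sensitivity", {
  # lorlatinib carries a reversible CYP3A4 Ki but no inactivation and no
  # co-administered perpetrator: the Ki never enters the single-drug model
  lor <- read_drug_config(alk_config("drugs", "lorlatinib.yaml"))
  phys <- default_human_physiology()
  sc <- local_scan(lor, phys, regimen("oral", 100, 24, 2),
                   panel = "ki_cyp3a4",
                   settings = simulation_settings(t_end_h = 48,
                                                  rtol = 1e-6, atol = 1e-8))
  expect_true(all(abs(sc$sc_central) < 1e-9))
})

test_that("unknown panel parameters are rejected", {
  lor <- read_drug_config(alk_config("drugs", "lorlatinib.yaml"))
  expect_error(local_scan(lor, default_human_physiology(),
                          regimen("oral", 100), panel = "banana"),
               "not found")
})

test_that("brain trough decreases monotonically with P-gp expression", {
  pm <- patient_model("crizotinib")
  scan <- pgp_expression_scan(
    pm$drugs, pm$physiology, regimen("oral", 250, 12, 8),
    expression_grid = c(0, 0.85, 1.7, 3.4),
    settings = simulation_settings(t_end_h = 96, rtol = 1e-6, atol = 1e-8))
  expect_true(all(diff(scan$ctrough_brain_uM) < 0))
  expect_equal(attr(scan, "baseline_expression_uM"), 1.7, tolerance = 1e-9)
  expect_gt(attr(scan, "fold_change_efflux_absent"), 1)
  # grid refinement does not move the endpoints beyond solver noise
  scan2 <- pgp_expression_scan(
    pm$drugs, pm$physiology, regimen("oral", 250, 12, 8),
    expression_grid = c(0, 1.7, 3.4),
    settings = simulation_settings(t_end_h = 96, rtol = 1e-6, atol = 1e-8))
  expect_equal(scan2$ctrough_brain_uM[c(1, 3)],
               scan$ctrough_brain_uM[c(1, 4)], tolerance = 1e-4)
})
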