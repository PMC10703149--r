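test_that("ddi ratio arithmetic reproduces tabulated predicted ratios", {
  expect_equal(ddi_ratio(list(auc = 1, cmax = 1),
                         list(auc = 1, cmax = 1))$auc_ratio, 1)
  r <- ddi_ratio(list(auc = 5452, cmax = 100), list(auc = 1590, cmax = 70))
  expect_equal(round_half_up(r$auc_ratio, 2), 3.43)
  r2 <- ddi_ratio(list(auc = 1726, cmax = 374), list(auc = 7021, cmax = 692))
  expect_equal(round_half_up(r2$cmax_ratio, 2), 0.54)
  expect_error(ddi_ratio(list(auc = 1, cmax = 1), list(auc = 0, cmax = 1)))
  # reciprocity under swapping the arms
  a <- list(auc = 321, cmax = 45); b <- list(auc = 1234, cmax = 77)
  expect_equal(ddi_ratio(a, b)$auc_ratio * ddi_ratio(b, a)$auc_ratio, 1,
               tolerance = 1e-12)
})

test_that("a perpetrator without interaction parameters leaves the victim unchanged", {
  victim <- probe_drug("victim", cl_plasma_lph = 8)
  ghost <- probe_drug("ghost", cl_plasma_lph = 8)
  phys <- mixing_physiology(50)
  dsg <- ddi_design(regimen("iv_bolus", 10),
                    regimen("iv_bolus", 10, 24, 2), 72)
  dr <- co_simulate(victim, ghost, phys, dsg, fast_settings(72))
  expect_equal(dr$auc_ratio, 1, tolerance = 1e-6)
  expect_equal(dr$cmax_ratio, 1, tolerance = 1e-6)
})

test_that("constant competitive inhibition at I = Ki doubles the victim AUC", {
  # victim: fully CYP3A4-cleared, evenly partitioning; perpetrator: no
  # elimination, held at a liver unbound concentration equal to its Ki
  victim <- probe_drug("victim", cl_plasma_lph = 0)
  victim$pathways <- list(enzyme_pathway("CYP3A4", cl_int = 2,
                                         cl_int_basis = "per_mg_protein"))
  perp <- probe_drug("blocker", cl_plasma_lph = 0)
  perp$interaction <- interaction_parameters(ki_cyp3a4 = 1)
  phys <- mixing_physiology(1000)
  m_perp <- build_model(perp, phys)
  v_eff <- effective_volume(m_perp)
  dose_perp_mg <- 1 * v_eff * 400 / 1000   # 1 uM everywhere
  cl_u <- 2 * 6e-5 * 45 * phys$liver$mass_g
  dsg <- ddi_design(regimen("iv_bolus", 2),
                    regimen("iv_bolus", dose_perp_mg), 240)
  dr <- co_simulate(victim, perp, phys, dsg,
                    simulation_settings(t_end_h = 240, rtol = 1e-8,
                                        atol = 1e-10))
  # tail-correct both arms to AUC(0, inf)
  v_vic <- effective_volume(build_model(victim, phys))
  tail_alone <- dr$result_alone$profiles$victim$plasma_total_ngml
  tail_comb <- dr$result_combined$profiles$victim$plasma_total_ngml
  auc_alone <- dr$alone$auc + tail_alone[length(tail_alone)] * v_vic / cl_u
  auc_comb <- dr$combined$auc +
    tail_comb[length(tail_comb)] * v_vic / (cl_u / 2)
  expect_equal(auc_comb / auc_alone, 2, tolerance = 0.02)
})

test_that("shipped modulators shift a CYP3A4 probe victim in the right direction", {
  mdz <- read_drug_config(alk_config("perpetrators",
                                     "midazolam-placeholder.yaml"))
  phys <- default_human_physiology()
  st <- simulation_settings(rtol = 1e-6, atol = 1e-8)
  keto <- read_drug_config(alk_config("perpetrators",
                                      "ketoconazole-placeholder.yaml"))
  dsg <- ddi_design(regimen("oral", 5, start_h = 96),
                    regimen("oral", 200, 12, 12), 168)
  inh <- co_simulate(mdz, keto, phys, dsg, st)
  expect_gt(inh$auc_ratio, 1)
  rif <- read_drug_config(alk_config("perpetrators",
                                     "rifampin-placeholder.yaml"))
  dsg2 <- ddi_design(regimen("oral", 5, start_h = 120),
                     regimen("oral", 600, 24, 7), 192)
  ind <- co_simulate(mdz, rif, phys, dsg2, st)
  expect_lt(ind$auc_ratio, 1)
})

test_that("inconsistent schedules are rejected", {
  expect_error(ddi_design(regimen("oral", 100, start_h = 100),
                          regimen("oral", 100), 96), "inconsistent")
})
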