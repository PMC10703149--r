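test_that("occupancy follows the saturation law", {
  expect_equal(occupancy(0, 5), 0)
  expect_equal(occupancy(10, 10), 50)
  expect_equal(round_half_up(occupancy(78.2, 10), 1), 88.7)
  expect_error(occupancy(1, 0))
  # strictly increasing in concentration, decreasing in Ki, bounded
  conc <- c(0.01, 0.1, 1, 10, 100, 1e4)
  ao <- occupancy(conc, 17)
  expect_true(all(diff(ao) > 0))
  expect_true(all(ao >= 0 & ao < 100))
  kis <- c(0.8, 1, 4, 29)
  at_fixed <- vapply(kis, function(k) occupancy(11, k), 0)
  expect_true(all(diff(at_fixed) < 0))
})

test_that("occupancy ordering across variants reverses the Ki ordering", {
  kis <- c(`wild-type` = 10, L1196M = 446, G1269A = 250, G1202R = 191)
  ao <- vapply(kis, function(k) occupancy(78.2, k), 0)
  expect_equal(order(ao), rev(order(kis)))
})

test_that("CSF mapping respects the ratio provenance and is linear", {
  expect_equal(csf_concentration(c(1, 5, 10), 0.43, 0), c(0, 0, 0))
  # unbound-referenced ratio: lorlatinib trough 160 nM unbound -> 123 nM CSF
  total_nM <- 160 / 0.43
  expect_equal(signif(csf_concentration(total_nM, 0.43, 0.77, "unbound"), 3),
               123)
  expect_equal(csf_concentration(7.7, 1, 1, "unbound"), 7.7)
  # total-referenced ratio multiplies total plasma directly
  expect_equal(csf_concentration(100, 0.13, 0.0026, "total"), 0.26)
  # linear in both the profile and the ratio
  x <- c(1, 2, 8)
  expect_equal(csf_concentration(3 * x, 0.4, 0.7, "unbound"),
               3 * csf_concentration(x, 0.4, 0.7, "unbound"))
  expect_equal(csf_concentration(x, 0.4, 1.4, "unbound"),
               2 * csf_concentration(x, 0.4, 0.7, "unbound"))
})

test_that("unit conversion is exact and involutive", {
  expect_equal(unit_convert(450.3, 450.3, "ngml_to_nM"), 1000)
  expect_equal(unit_convert(0, 406.4, "ngml_to_nM"), 0)
  expect_equal(round_half_up(unit_convert(65.0, 406.4, "ngml_to_nM"), 1),
               159.9)
  x <- c(0.31, 12, 5066)
  expect_equal(unit_convert(unit_convert(x, 482.6, "ngml_to_nM"),
                            482.6, "nM_to_ngml"), x, tolerance = 1e-12)
  expect_error(unit_convert(1, 0))
})

test_that("regimen assessment reproduces tabulated occupancy rows", {
  ale <- read_drug_config(alk_config("drugs", "alectinib.yaml"))
  variants <- read_alk_variants("alectinib")
  # subjects all at the tabulated unbound plasma trough of 11.0 nM
  total_ngml <- rep(unit_convert(11.0 / ale$fup_patient, 482.6,
                                 "nM_to_ngml"), 6)
  out <- assess_regimen(total_ngml, ale, variants)
  pl <- out[out$site == "plasma", ]
  expect_equal(round_half_up(pl$min_ao_pct[pl$variant == "wild-type"], 1), 91.7)
  expect_equal(round_half_up(pl$min_ao_pct[pl$variant == "L1196M"], 1), 93.2)
  expect_equal(round_half_up(pl$min_ao_pct[pl$variant == "G1269A"], 1), 73.3)
  expect_equal(round_half_up(pl$min_ao_pct[pl$variant == "G1202R"], 1), 27.5)
  expect_true(pl$pass_ao[pl$variant == "L1196M"])
  expect_false(pl$pass_ao[pl$variant == "G1202R"])

  cri <- read_drug_config(alk_config("drugs", "crizotinib.yaml"))
  cvar <- read_alk_variants("crizotinib")
  total_cri <- rep(unit_convert(78.2 / 0.13, 450.3, "nM_to_ngml"), 6)
  outc <- assess_regimen(total_cri, cri, cvar)
  csf_wt <- outc[outc$site == "csf" & outc$variant == "wild-type", ]
  expect_equal(round_half_up(csf_wt$ctrough_unbound_nM, 2), 1.56)
  expect_equal(round_half_up(csf_wt$min_ao_pct, 1), 13.5)
  expect_false(csf_wt$pass_ao)
  # plasma wild-type passes both trough (235 ng/mL) and occupancy gates
  pl_wt <- outc[outc$site == "plasma" & outc$variant == "wild-type", ]
  expect_true(pl_wt$pass_ctrough && pl_wt$pass_ao && pl_wt$pass)
})

test_that("assessment at exact thresholds passes the boundary", {
  d <- probe_drug()
  d$k_csf_p <- 1
  d$k_csf_reference <- "unbound_plasma"
  v <- alk_variant("wild-type", ki = 100, ctrough_threshold = 400)
  # unbound = total (fup 1); 400 ng/mL = 1000 nM -> AO 90.9 > 75
  out <- assess_regimen(rep(400, 5), d, list(v))
  expect_true(all(out$pass))
  expect_error(assess_regimen(c(400, -1), d, list(v)))
})
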