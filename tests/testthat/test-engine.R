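test_that("Weibull dissolution is anchored at the 50% time", {
  expect_equal(weibull_fraction_dissolved(0, 45, 0.92), 0)
  expect_equal(weibull_fraction_dissolved(45, 45, 0.92), 0.5)
  expect_equal(weibull_fraction_dissolved(90, 45, 0.92), 0.731,
               tolerance = 0.001 / 0.731)
  for (t50 in c(30, 45, 60)) {
    expect_equal(weibull_fraction_dissolved(t50, t50, 0.92), 0.5)
  }
  expect_error(weibull_fraction_dissolved(10, 0, 1))
})

test_that("enzyme turnover rates recover limits and half-saturation", {
  kdeg <- log(2) / 36
  # no perturbation: relaxation to baseline
  p0 <- interaction_parameters(ki_cyp3a4 = 1.9)
  expect_equal(enzyme_interaction_rates(0.5, 0, p0, kdeg), kdeg * 0.5)
  expect_equal(enzyme_interaction_rates(1, 0, p0, kdeg), 0)
  # induction only, saturating inducer: steady state at E0 * (1 + Emax)
  pind <- interaction_parameters(ki_cyp3a4 = 1, emax_cyp3a4 = 10.4,
                                 ec50_cyp3a4 = 1e-9)
  e_ss <- 1 + 10.4
  expect_equal(enzyme_interaction_rates(e_ss, 1e6, pind, kdeg), 0,
               tolerance = 1e-4)
  # half-saturated inactivation: loss term kinact/2 * E
  ptdi <- interaction_parameters(ki_cyp3a4 = 1.9, kinact_cyp3a4 = 6.6)
  expect_equal(enzyme_interaction_rates(1, 1.9, ptdi, kdeg, e0 = 1), -3.3)
})

test_that("renal-only clearance reduces to GFR * fup * fraction", {
  d <- probe_drug(cl_plasma_lph = 0, gfr_fraction = 1)
  d$fup_healthy <- 0.5
  phys <- default_human_physiology()
  phys$gfr <- 120
  model <- build_model(d, phys)
  cl_plasma <- model$species[[1]]$renal_cl_u * d$fup_healthy
  expect_equal(cl_plasma, 120 * 60 / 1000 * 0.5)  # 3.6 L/h
})

test_that("alectinib model carries M4 with its own patient binding", {
  pm <- patient_model("alectinib")
  expect_true("alectinib-m4" %in% names(pm$model$species))
  m4 <- pm$model$species[["alectinib-m4"]]
  expect_equal(m4$fup, 0.009)
  expect_equal(m4$rbp, 2.8)
  # parent CYP3A4 flux is routed into M4
  prod <- vapply(pm$model$species$alectinib$paths, function(p)
    p$product, "")
  expect_true("alectinib-m4" %in% prod)
})

test_that("without any clearance process nothing is eliminated", {
  d <- probe_drug(cl_plasma_lph = 0, gfr_fraction = 0)
  model <- build_model(d, mixing_physiology(10))
  res <- simulate_pbpk(model, regimen("iv_bolus", 10),
                       fast_settings(24))
  last <- res$state[nrow(res$state), ]
  elim <- sum(last[paste0(c("cum_met", "cum_renal", "cum_add"), ".probe")])
  expect_lt(elim, 1e-10)
  expect_equal(mass_balance(res)$max_rel_error, 0, tolerance = 1e-8)
})

test_that("engine reproduces the one-compartment closed form within 0.1%", {
  cl <- 6
  d <- probe_drug(cl_plasma_lph = cl)
  model <- build_model(d, mixing_physiology(1000))
  dose_mg <- 10
  res <- simulate_pbpk(model, regimen("iv_bolus", dose_mg),
                       fast_settings(72))
  v <- effective_volume(model)
  d_umol <- dose_mg / 400 * 1000
  pr <- res$profiles$probe
  sel <- pr$time >= 0.5
  analytic <- d_umol / v * exp(-cl * pr$time[sel] / v)
  expect_lt(max(abs(pr$plasma_total_uM[sel] - analytic) / analytic), 1e-3)
  # AUC from 0.5 h to infinity equals the closed-form integral (the bolus
  # discontinuity at t = 0 is excluded from the quadrature)
  m <- pk_metrics(res, "probe", "plasma_total_uM", window = c(0.5, 72))
  auc_inf <- m$auc + pr$plasma_total_uM[nrow(pr)] * v / cl
  expect_equal(auc_inf, d_umol / cl * exp(-cl * 0.5 / v), tolerance = 1e-3)
})

test_that("engine reproduces the two-compartment closed form within 0.1%", {
  cl <- 6
  d <- probe_drug(cl_plasma_lph = cl)
  d$log_p <- 8      # very fast membranes; binding is zeroed in the physiology
  phys <- lipid_free(mixing_physiology(1000))
  i_mus <- which(phys$organs$organ == "muscle")
  # small vascular exchange surface makes muscle a distinct peripheral
  # compartment; intracellular exchange stays fast
  ps_target <- 4
  phys$organs$sa_factor[i_mus] <-
    ps_target * 1000 / (d$permeability_papp * 3600 *
                          phys$organs$volume_l[i_mus])
  model <- build_model(d, phys)
  sp <- model$species[[1]]
  v2 <- model$v_int[i_mus] * sp$kpu_int[i_mus] +
    model$v_cell[i_mus] * sp$kpu_cell[i_mus]
  v1 <- effective_volume(model) - v2
  q12 <- sp$ps1[i_mus]
  k10 <- cl / v1; k12 <- q12 / v1; k21 <- q12 / v2
  s <- k10 + k12 + k21
  alpha <- (s + sqrt(s^2 - 4 * k10 * k21)) / 2
  beta <- (s - sqrt(s^2 - 4 * k10 * k21)) / 2
  dose_mg <- 10
  d_umol <- dose_mg / 400 * 1000
  res <- simulate_pbpk(model, regimen("iv_bolus", dose_mg),
                       fast_settings(96))
  pr <- res$profiles$probe
  sel <- pr$time >= 0.5
  tt <- pr$time[sel]
  analytic <- d_umol / v1 * ((alpha - k21) / (alpha - beta) * exp(-alpha * tt) +
                               (k21 - beta) / (alpha - beta) * exp(-beta * tt))
  expect_lt(max(abs(pr$plasma_total_uM[sel] - analytic) / analytic), 1e-3)
})

test_that("zero dose yields an identically zero simulation", {
  d <- probe_drug()
  model <- build_model(d, mixing_physiology(10))
  res <- simulate_pbpk(model, regimen("oral", 0), fast_settings(12))
  expect_true(all(res$profiles$probe$plasma_total_uM == 0))
})

test_that("doubling the dose doubles AUC under linear kinetics", {
  pm <- patient_model("lorlatinib")   # first-order + far-below-Km MM
  drugs <- pm$drugs
  drugs[[1]]$interaction <- NULL      # remove auto-induction nonlinearity
  model <- build_model(drugs, pm$physiology)
  st <- simulation_settings(t_end_h = 48, rtol = 1e-8, atol = 1e-10)
  m <- lapply(c(1, 2), function(dose) {
    res <- simulate_pbpk(model, list(lorlatinib = regimen("oral", dose)), st)
    pk_metrics(res, "lorlatinib")
  })
  expect_equal(m[[2]]$auc / m[[1]]$auc, 2, tolerance = 2e-3)
})

test_that("mass balance holds through oral dosing, metabolism and formation", {
  pm <- patient_model("alectinib")
  st <- simulation_settings(t_end_h = 72, rtol = 1e-8, atol = 1e-10)
  res <- simulate_pbpk(pm$model,
                       list(alectinib = regimen("oral", 600, 12, 6)), st)
  mb <- mass_balance(res)
  expect_lt(max(mb$max_rel_error), 1e-6)
  # all mass states stay non-negative (within solver noise); bookkeeping
  # columns (dose clocks) are not amounts
  mass_cols <- !grepl("^(t_dose|inf_rate)", colnames(res$state))
  expect_gt(min(res$state[, mass_cols][, -1]), -1e-6)
})

test_that("repeated doses superpose when interaction parameters are zeroed", {
  d <- probe_drug(cl_plasma_lph = 20, papp = 3e-5)
  model <- build_model(d, mixing_physiology(50))
  st <- simulation_settings(t_end_h = 72, dt_out_h = 0.5,
                            rtol = 1e-8, atol = 1e-10)
  single <- simulate_pbpk(model, regimen("oral", 100), st)
  multi <- simulate_pbpk(model, regimen("oral", 100, interval_h = 12,
                                        n_doses = 4), st)
  cs <- single$profiles$probe$plasma_total_uM
  tt <- single$profiles$probe$time
  super <- cs
  for (k in 1:3) {
    shift <- k * 12 / 0.5
    super <- super + c(rep(0, shift), cs[1:(length(cs) - shift)])
  }
  cm <- multi$profiles$probe$plasma_total_uM
  keep <- tt > 1 & abs(tt %% 12) > 0.9   # avoid the absorption spikes
  expect_lt(max(abs(cm[keep] - super[keep]) /
                  pmax(super[keep], max(super) * 1e-3)), 0.01)
})

test_that("PK metrics follow their defining arithmetic", {
  fake <- structure(list(
    profiles = list(x = data.frame(time = seq(0, 10, 0.5),
                                   plasma_total_ngml = 7))
  ), class = "simulation_result")
  m <- pk_metrics(fake, "x")
  expect_equal(m$auc, 70)
  expect_equal(m$cmax, 7)
  expect_equal(m$ctrough, 7)
  tt <- seq(0, 48, 0.05)
  dec <- structure(list(
    profiles = list(x = data.frame(time = tt,
                                   plasma_total_ngml = 100 * exp(-0.2 * tt)))
  ), class = "simulation_result")
  md <- pk_metrics(dec, "x")
  auc_inf <- md$auc + md$ctrough / 0.2
  expect_equal(auc_inf, 100 / 0.2, tolerance = 1e-3)
  expect_error(pk_metrics(fake, "x", window = c(5, 5)), "fewer than two")
})

test_that("halving solver tolerances leaves metrics unchanged to 0.01%", {
  pm <- patient_model("crizotinib")
  reg <- list(crizotinib = regimen("oral", 250, 12, 4))
  m <- lapply(c(1, 0.5), function(f) {
    st <- simulation_settings(t_end_h = 48, rtol = 1e-8 * f, atol = 1e-10 * f)
    pk_metrics(simulate_pbpk(pm$model, reg, st), "crizotinib")
  })
  for (fld in c("auc", "cmax", "ctrough")) {
    expect_equal(m[[2]][[fld]] / m[[1]][[fld]], 1, tolerance = 1e-4)
  }
})
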