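#' Local sensitivity coefficient
#'
#' Normalised ratio of output change to parameter change:
#' `SC = ((y1 - y0)/y0) / ((p1 - p0)/p0)`.
#'
#' @param y0,y1 Output before/after perturbation (`y0 != 0`).
#' @param p0,p1 Parameter before/after perturbation (`p0 != 0`, `p1 != p0`).
#' @return The sensitivity coefficient.
#' @export
sensitivity_coefficient <- function(y0, y1, p0, p1) {
  if (y0 == 0 || p0 == 0) stop("zero baseline in sensitivity coefficient")
  if (p1 == p0) stop("parameter perturbation is zero")
  ((y1 - y0) / y0) / ((p1 - p0) / p0)
}

# perturbable parameters: returns modified (drugs, physiology) copies
.apply_perturbation <- function(drugs, physiology, param, factor) {
  d <- drugs[[1]]
  if (param == "log_p") {
    for (s in seq_along(drugs)) drugs[[s]]$log_p <- drugs[[s]]$log_p * factor
  } else if (param == "fup") {
    for (s in seq_along(drugs)) {
      drugs[[s]]$fup_healthy <- min(1, drugs[[s]]$fup_healthy * factor)
      if (!is.na(drugs[[s]]$fup_patient)) {
        drugs[[s]]$fup_patient <- min(1, drugs[[s]]$fup_patient * factor)
      }
    }
  } else if (param == "rbp") {
    for (s in seq_along(drugs)) {
      drugs[[s]]$rbp_healthy <- drugs[[s]]$rbp_healthy * factor
      if (!is.na(drugs[[s]]$rbp_patient)) {
        drugs[[s]]$rbp_patient <- drugs[[s]]$rbp_patient * factor
      }
    }
  } else if (grepl("^cl_int_", param)) {
    enz <- sub("^cl_int_", "", param)
    hit <- FALSE
    for (k in seq_along(d$pathways)) {
      if (d$pathways[[k]]$enzyme == enz && !is.null(d$pathways[[k]]$cl_int)) {
        d$pathways[[k]]$cl_int <- d$pathways[[k]]$cl_int * factor
        hit <- TRUE
      }
    }
    if (!hit && enz != "Pgp") stop("parameter not found: ", param)
    drugs[[1]] <- d
  } else if (param == "vmax_CYP3A4" || param == "km_CYP3A4") {
    fld <- if (param == "vmax_CYP3A4") "v_max" else "k_m"
    hit <- FALSE
    for (k in seq_along(d$pathways)) {
      if (d$pathways[[k]]$enzyme == "CYP3A4" &&
          !is.null(d$pathways[[k]][[fld]])) {
        d$pathways[[k]][[fld]] <- d$pathways[[k]][[fld]] * factor
        hit <- TRUE
      }
    }
    if (!hit) stop("parameter not found: ", param)
    drugs[[1]] <- d
  } else if (param == "cl_int_pgp") {
    if (!length(d$transporters)) stop("parameter not found: ", param)
    for (k in seq_along(d$transporters)) {
      d$transporters[[k]]$cl_int <- d$transporters[[k]]$cl_int * factor
    }
    drugs[[1]] <- d
  } else if (param %in% c("ki_cyp3a4", "ec50_cyp3a4", "emax_cyp3a4",
                          "kinact_cyp3a4")) {
    if (is.null(d$interaction) || is.null(d$interaction[[param]])) {
      stop("parameter not found: ", param)
    }
    d$interaction[[param]] <- d$interaction[[param]] * factor
    drugs[[1]] <- d
  } else if (grepl("^expression_", param)) {
    mol <- sub("^expression_", "", param)
    mol <- sub("^Pgp$", "P-gp", mol)
    et <- physiology$expression_table
    i <- match(mol, et$molecule)
    if (is.na(i)) stop("parameter not found: ", param)
    et$reference_conc_uM[i] <- et$reference_conc_uM[i] * factor
    physiology$expression_table <- et
  } else {
    stop("parameter not found: ", param)
  }
  list(drugs = drugs, physiology = physiology)
}

#' Local sensitivity scan
#'
#' Perturbs each panel parameter by `+/- perturbation`, re-simulates the
#' regimen and reports sensitivity coefficients for AUC, Cmax and Ctrough of
#' the final dosing interval. `|SC| > 1` is flagged as significant.
#'
#' @param drugs Drug parameter set (first species is perturbed and reported).
#' @param physiology A [physiology_parameters()] object.
#' @param reg A [regimen()] (the full schedule simulated; metrics are taken
#'   over the final interval).
#' @param panel Character vector of parameter names: `"log_p"`, `"fup"`,
#'   `"rbp"`, `"cl_int_<ENZYME>"`, `"vmax_CYP3A4"`, `"km_CYP3A4"`,
#'   `"cl_int_pgp"`, `"ki_cyp3a4"`, `"ec50_cyp3a4"`, `"emax_cyp3a4"`,
#'   `"kinact_cyp3a4"`, `"expression_<MOLECULE>"`.
#' @param perturbation Relative perturbation (default 0.20).
#' @param settings [simulation_settings()] covering the regimen.
#' @param engine Engine constants.
#' @return Data frame: `parameter`, `output`, `sc_up`, `sc_down`,
#'   `sc_central`, `significant`.
#' @export
local_scan <- function(drugs, physiology, reg, panel,
                       perturbation = 0.20,
                       settings = simulation_settings(t_end_h = 96),
                       engine = engine_defaults()) {
  if (inherits(drugs, "drug_parameters")) drugs <- list(drugs)
  sp <- drugs[[1]]$name
  run <- function(dd, pp) {
    model <- build_model(dd, pp, engine)
    res <- simulate_pbpk(model, setNames(list(reg), sp), settings)
    last <- settings$t_end_h
    win <- c(max(0, last - reg$interval_h), last)
    m <- pk_metrics(res, sp, window = win)
    c(AUC = m$auc, Cmax = m$cmax, Ctrough = m$ctrough)
  }
  base <- run(drugs, physiology)
  rows <- list()
  for (param in panel) {
    up <- .apply_perturbation(drugs, physiology, param, 1 + perturbation)
    dn <- .apply_perturbation(drugs, physiology, param, 1 - perturbation)
    y_up <- run(up$drugs, up$physiology)
    y_dn <- run(dn$drugs, dn$physiology)
    for (o in names(base)) {
      if (base[[o]] == 0) next
      sc_up <- sensitivity_coefficient(base[[o]], y_up[[o]], 1,
                                       1 + perturbation)
      sc_dn <- sensitivity_coefficient(base[[o]], y_dn[[o]], 1,
                                       1 - perturbation)
      scc <- mean(c(sc_up, sc_dn))
      rows[[length(rows) + 1]] <- data.frame(
        parameter = param, output = o, sc_up = sc_up, sc_down = sc_dn,
        sc_central = scc, significant = abs(scc) > 1.0,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Brain P-gp expression scan
#'
#' Varies the P-gp concentration at the blood-brain barrier over a grid and
#' reports the brain-interstitial unbound trough concentration; the fold
#' change between absent efflux and the model baseline quantifies how
#' strongly the transporter limits brain exposure.
#'
#' @param drugs Drug parameter set with a brain P-gp efflux process
#'   (crizotinib).
#' @param physiology A [physiology_parameters()] object.
#' @param reg A [regimen()] (full schedule; trough at the end of the last
#'   interval).
#' @param expression_grid Brain-barrier P-gp concentrations, uM (the model
#'   baseline is `reference_conc * rel_brain` from the expression table).
#' @param settings,engine Simulation settings and engine constants.
#' @return Data frame `expression_uM`, `ctrough_brain_uM`, with attributes
#'   `baseline_expression_uM` and `fold_change_efflux_absent` (trough at zero
#'   expression over trough at baseline, when 0 is in the grid).
#' @export
pgp_expression_scan <- function(drugs, physiology, reg,
                                expression_grid = seq(0, 3.4, by = 0.85),
                                settings = simulation_settings(t_end_h = 96),
                                engine = engine_defaults()) {
  if (inherits(drugs, "drug_parameters")) drugs <- list(drugs)
  has_pgp <- any(vapply(drugs[[1]]$transporters, function(tr)
    tr$transporter == "P-gp" && tr$site == "brain", TRUE))
  if (!has_pgp) stop("first species has no brain P-gp efflux process")
  et <- physiology$expression_table
  i <- match("P-gp", et$molecule)
  baseline <- et$reference_conc_uM[i] * et$rel_brain[i]
  sp <- drugs[[1]]$name
  run <- function(expr_uM) {
    pp <- physiology
    pp$expression_table$rel_brain[i] <-
      expr_uM / pp$expression_table$reference_conc_uM[i]
    model <- build_model(drugs, pp, engine)
    res <- simulate_pbpk(model, setNames(list(reg), sp), settings)
    pr <- res$profiles[[sp]]
    pr$brain_interstitial_unbound_uM[length(pr$time)]
  }
  ct <- vapply(expression_grid, run, 0)
  out <- data.frame(expression_uM = expression_grid, ctrough_brain_uM = ct)
  attr(out, "baseline_expression_uM") <- baseline
  if (any(expression_grid == 0)) {
    base_ct <- if (any(abs(expression_grid - baseline) < 1e-9)) {
      ct[which.min(abs(expression_grid - baseline))]
    } else {
      run(baseline)
    }
    attr(out, "fold_change_efflux_absent") <- ct[expression_grid == 0][1] /
      base_ct
  }
  out
}
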