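#' Drug-drug interaction study design
#'
#' Victim and perpetrator schedules for a co-administration simulation. The
#' victim exposure window starts at the victim dose of interest (typically a
#' single dose given during steady-state perpetrator dosing) and runs to the
#' end of the simulation, approximating AUC to infinity.
#'
#' @param victim_regimen [regimen()] for the victim drug.
#' @param perpetrator_regimen [regimen()] for the perpetrator.
#' @param t_end_h Simulation span, h; must cover both schedules.
#' @return An object of class `ddi_design`.
#' @export
ddi_design <- function(victim_regimen, perpetrator_regimen, t_end_h) {
  stopifnot(inherits(victim_regimen, "regimen"),
            inherits(perpetrator_regimen, "regimen"))
  .check_scalar(t_end_h, "t_end_h", 0, open_lower = TRUE)
  v_last <- victim_regimen$start_h +
    (victim_regimen$n_doses - 1) * victim_regimen$interval_h
  p_last <- perpetrator_regimen$start_h +
    (perpetrator_regimen$n_doses - 1) * perpetrator_regimen$interval_h
  if (v_last >= t_end_h || p_last >= t_end_h) {
    stop("design schedule inconsistent: doses extend beyond t_end_h")
  }
  structure(list(victim = victim_regimen, perpetrator = perpetrator_regimen,
                 t_end_h = t_end_h),
            class = "ddi_design")
}

#' Victim/perpetrator co-simulation
#'
#' Simulates the victim alone and together with the perpetrator under
#' identical settings, coupling them through the shared hepatic CYP3A4 pool
#' (mechanism-based inactivation, induction) and competitive inhibition of
#' CYP3A4-mediated flux by the perpetrator's unbound hepatic concentration.
#' Exposure metrics are computed from the first victim dose to the end of
#' the simulation.
#'
#' @param victim Drug parameter set of the victim (a [drug_parameters()] or
#'   list including metabolites).
#' @param perpetrator A [drug_parameters()] object (the shipped placeholder
#'   perpetrators are in `alk_config("perpetrators")`).
#' @param physiology A [physiology_parameters()] object.
#' @param design A [ddi_design()] object.
#' @param settings [simulation_settings()]; `t_end_h` is taken from the
#'   design.
#' @param engine Engine constants.
#' @return An object of class `ddi_result`: victim AUC and Cmax alone and
#'   combined (total plasma, ng/mL basis) and their ratios.
#' @export
co_simulate <- function(victim, perpetrator, physiology, design,
                        settings = simulation_settings(),
                        engine = engine_defaults()) {
  stopifnot(inherits(design, "ddi_design"),
            inherits(perpetrator, "drug_parameters"))
  if (inherits(victim, "drug_parameters")) victim <- list(victim)
  settings$t_end_h <- design$t_end_h
  v_name <- victim[[1]]$name
  window <- c(design$victim$start_h, design$t_end_h)

  model_alone <- build_model(victim, physiology, engine)
  res_alone <- simulate_pbpk(model_alone,
                             setNames(list(design$victim), v_name), settings)
  m_alone <- pk_metrics(res_alone, v_name, window = window,
                        interval_h = design$victim$interval_h)

  model_comb <- build_model(c(victim, list(perpetrator)), physiology, engine)
  doses <- setNames(list(design$victim, design$perpetrator),
                    c(v_name, perpetrator$name))
  res_comb <- simulate_pbpk(model_comb, doses, settings)
  m_comb <- pk_metrics(res_comb, v_name, window = window,
                       interval_h = design$victim$interval_h)

  ratios <- ddi_ratio(m_comb, m_alone)
  structure(
    list(victim = v_name, perpetrator = perpetrator$name,
         alone = m_alone, combined = m_comb,
         auc_ratio = ratios$auc_ratio, cmax_ratio = ratios$cmax_ratio,
         result_alone = res_alone, result_combined = res_comb),
    class = "ddi_result"
  )
}

#' @export
print.ddi_result <- function(x, ...) {
  cat(sprintf("<ddi_result> %s + %s\n  AUC ratio %.3g, Cmax ratio %.3g\n",
              x$victim, x$perpetrator, x$auc_ratio, x$cmax_ratio))
  invisible(x)
}

#' Exposure ratios of combined versus alone metrics
#'
#' @param combined,alone [pk_metrics()] objects (or lists with `auc`,
#'   `cmax`).
#' @return `list(auc_ratio, cmax_ratio)`.
#' @export
#' @examples
#' ddi_ratio(list(auc = 5452, cmax = 100), list(auc = 1590, cmax = 70))
ddi_ratio <- function(combined, alone) {
  if (!all(c("auc", "cmax") %in% names(combined)) ||
      !all(c("auc", "cmax") %in% names(alone))) {
    stop("inputs must carry 'auc' and 'cmax'")
  }
  if (alone$auc <= 0 || alone$cmax <= 0) {
    stop("reference (alone) metrics must be positive")
  }
  list(auc_ratio = combined$auc / alone$auc,
       cmax_ratio = combined$cmax / alone$cmax)
}

#' Shipped co-administration designs
#'
#' The studied co-administration schedules: a single victim dose given during
#' repeated perpetrator dosing.
#'
#' @param name One of `"cri_ketoconazole"`, `"cri_rifampin"`,
#'   `"ale_posaconazole"`, `"ale_rifampin"`, `"lor_itraconazole"`,
#'   `"lor_rifampin"`.
#' @return A list: `design` ([ddi_design()]) and `perpetrator_config` (file
#'   name under the shipped perpetrator directory).
#' @export
ddi_design_library <- function(name = c("cri_ketoconazole", "cri_rifampin",
                                        "ale_posaconazole", "ale_rifampin",
                                        "lor_itraconazole", "lor_rifampin")) {
  name <- match.arg(name)
  day <- function(d) (d - 1) * 24
  spec <- switch(name,
    cri_ketoconazole = list(
      victim = regimen("oral", 150, start_h = day(4)),
      perp = regimen("oral", 200, interval_h = 12, n_doses = 32),
      t_end = day(17), file = "ketoconazole-placeholder.yaml"),
    cri_rifampin = list(
      victim = regimen("oral", 250, start_h = day(9)),
      perp = regimen("oral", 600, interval_h = 24, n_doses = 14),
      t_end = day(22), file = "rifampin-placeholder.yaml"),
    ale_posaconazole = list(
      victim = regimen("oral", 300, start_h = day(6)),
      perp = regimen("oral", 400, interval_h = 12, n_doses = 28),
      t_end = day(15), file = "posaconazole-placeholder.yaml"),
    ale_rifampin = list(
      victim = regimen("oral", 150, start_h = day(6)),
      perp = regimen("oral", 600, interval_h = 24, n_doses = 14),
      t_end = day(15), file = "rifampin-placeholder.yaml"),
    lor_itraconazole = list(
      victim = regimen("oral", 150, start_h = day(5)),
      perp = regimen("oral", 200, interval_h = 24, n_doses = 11),
      t_end = day(12), file = "itraconazole-placeholder.yaml"),
    lor_rifampin = list(
      victim = regimen("oral", 150, start_h = day(13)),
      perp = regimen("oral", 600, interval_h = 24, n_doses = 12,
                     start_h = day(6)),
      t_end = day(19), file = "rifampin-placeholder.yaml")
  )
  list(design = ddi_design(spec$victim, spec$perp, spec$t_end),
       perpetrator_config = spec$file)
}
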