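#' Metabolic pathway of a drug
#'
#' One enzyme-mediated clearance process. Exactly one kinetic form must be
#' given: first-order intrinsic clearance (`cl_int` with its unit basis) or
#' Michaelis-Menten (`v_max` + `k_m`).
#'
#' @param enzyme One of `"CYP3A4"`, `"CYP3A5"`, `"CYP2C8"`, `"CYP2C19"`,
#'   `"UGT1A3"`, `"UGT1A4"`, `"HLM"` (unspecified human-liver-microsome
#'   clearance, not attributed to an inducible/inhibitable enzyme).
#' @param cl_int First-order intrinsic clearance (> 0), on the basis given by
#'   `cl_int_basis`.
#' @param cl_int_basis `"per_pmol_enzyme"` (uL/min/pmol) or
#'   `"per_mg_protein"` (uL/min/mg microsomal protein).
#' @param v_max Maximum velocity, pmol/min/mg microsomal protein (> 0).
#' @param k_m Michaelis constant, uM (> 0).
#' @param isef Intersystem extrapolation factor applied to `cl_int` when the
#'   velocity comes from a recombinant system; `NA` means none/already applied.
#' @param product Metabolite species id receiving the molar flux, or `"sink"`.
#' @return An object of class `enzyme_pathway`.
#' @export
enzyme_pathway <- function(enzyme, cl_int = NULL,
                           cl_int_basis = c("per_pmol_enzyme", "per_mg_protein"),
                           v_max = NULL, k_m = NULL, isef = NA_real_,
                           product = "sink") {
  enzyme <- match.arg(enzyme, c("CYP3A4", "CYP3A5", "CYP2C8", "CYP2C19",
                                "UGT1A3", "UGT1A4", "HLM"))
  has_fo <- !is.null(cl_int)
  has_mm <- !is.null(v_max) || !is.null(k_m)
  if (has_fo == has_mm) {
    stop("exactly one kinetics form must be set: cl_int OR v_max + k_m")
  }
  if (has_fo) {
    .check_scalar(cl_int, "cl_int", 0, open_lower = TRUE)
    cl_int_basis <- match.arg(cl_int_basis)
  } else {
    .check_scalar(v_max, "v_max", 0, open_lower = TRUE)
    .check_scalar(k_m, "k_m", 0, open_lower = TRUE)
    cl_int_basis <- NA_character_
  }
  if (!is.na(isef)) .check_scalar(isef, "isef", 0, open_lower = TRUE)
  structure(
    list(enzyme = enzyme, cl_int = cl_int, cl_int_basis = cl_int_basis,
         v_max = v_max, k_m = k_m, isef = isef, product = product),
    class = "enzyme_pathway"
  )
}

#' Transporter process (P-gp efflux)
#'
#' @param transporter Currently only `"P-gp"`.
#' @param cl_int Intrinsic transport velocity, uL/min/10^6 cells (> 0).
#' @param k_m Michaelis constant of the transporter, uM (> 0).
#' @param site Barrier where the efflux acts; `"brain"` means brain
#'   interstitial -> plasma at the blood-brain barrier.
#' @param direction Only `"efflux"`.
#' @return An object of class `transporter_process`.
#' @export
transporter_process <- function(transporter = "P-gp", cl_int, k_m,
                                site = "brain", direction = "efflux") {
  transporter <- match.arg(transporter)
  direction <- match.arg(direction)
  .check_scalar(cl_int, "cl_int", 0, open_lower = TRUE)
  .check_scalar(k_m, "k_m", 0, open_lower = TRUE)
  structure(
    list(transporter = transporter, cl_int = cl_int, k_m = k_m,
         site = site, direction = direction),
    class = "transporter_process"
  )
}

#' Enzyme interaction parameters of a perpetrator species
#'
#' Reversible (competitive) CYP3A4 inhibition (`ki_cyp3a4`), mechanism-based
#' inactivation (`kinact_cyp3a4`, with `ki_cyp3a4` as the half-maximal
#' inactivation concentration), induction (`emax_cyp3a4`, `ec50_cyp3a4`) and
#' an optional P-gp Ki carried for completeness.
#'
#' @param ki_cyp3a4 uM (> 0) or `NULL`.
#' @param kinact_cyp3a4 1/h (> 0) or `NULL`.
#' @param emax_cyp3a4 Unitless maximum fold-increase of synthesis (> 0) or
#'   `NULL`.
#' @param ec50_cyp3a4 uM (> 0) or `NULL`.
#' @param ki_pgp uM (> 0) or `NULL`.
#' @return An object of class `interaction_parameters`.
#' @export
interaction_parameters <- function(ki_cyp3a4 = NULL, kinact_cyp3a4 = NULL,
                                   emax_cyp3a4 = NULL, ec50_cyp3a4 = NULL,
                                   ki_pgp = NULL) {
  .check_scalar(ki_cyp3a4, "ki_cyp3a4", 0, open_lower = TRUE, allow_null = TRUE)
  .check_scalar(kinact_cyp3a4, "kinact_cyp3a4", 0, open_lower = TRUE,
                allow_null = TRUE)
  .check_scalar(emax_cyp3a4, "emax_cyp3a4", 0, open_lower = TRUE,
                allow_null = TRUE)
  .check_scalar(ec50_cyp3a4, "ec50_cyp3a4", 0, open_lower = TRUE,
                allow_null = TRUE)
  .check_scalar(ki_pgp, "ki_pgp", 0, open_lower = TRUE, allow_null = TRUE)
  if (!is.null(kinact_cyp3a4) && is.null(ki_cyp3a4)) {
    stop("kinact_cyp3a4 requires ki_cyp3a4 (half-maximal inactivation conc)")
  }
  if (xor(is.null(emax_cyp3a4), is.null(ec50_cyp3a4))) {
    stop("emax_cyp3a4 and ec50_cyp3a4 must be given together")
  }
  structure(
    list(ki_cyp3a4 = ki_cyp3a4, kinact_cyp3a4 = kinact_cyp3a4,
         emax_cyp3a4 = emax_cyp3a4, ec50_cyp3a4 = ec50_cyp3a4,
         ki_pgp = ki_pgp),
    class = "interaction_parameters"
  )
}

#' Drug (or metabolite) parameter set
#'
#' The physicochemical, binding, absorption, distribution, metabolism and
#' interaction parameters of one chemical species.
#'
#' @param name Species identifier.
#' @param molecular_weight g/mol (> 0).
#' @param pka_list List of `list(value=, type="base"|"acid")` entries; may be
#'   empty for a neutral compound.
#' @param log_p Octanol-water lipophilicity.
#' @param solubility mg/mL (informational; dissolution is Weibull-driven).
#' @param permeability_papp Apparent permeability, cm/s (> 0).
#' @param fup_healthy,fup_patient Unbound plasma fraction, (0, 1];
#'   `fup_patient` may be `NA` and derived via [apply_cancer_physiology()].
#' @param rbp_healthy,rbp_patient Blood-to-plasma ratio (> 0; patient may be
#'   `NA`).
#' @param gfr_fraction Fraction of filtered drug excreted in urine.
#' @param kia_scale,kir_scale Intracellular / interstitial partition
#'   multipliers.
#' @param weibull_t50 Time to 50% dissolution, min (> 0).
#' @param weibull_shape Weibull shape parameter (> 0).
#' @param cl_additional Additional plasma clearance, L/h/kg, or `NULL`.
#' @param k_csf_p CSF-to-plasma concentration ratio (>= 0).
#' @param k_csf_reference `"total_plasma"` or `"unbound_plasma"`: which plasma
#'   concentration the ratio refers to.
#' @param pathways List of [enzyme_pathway()] objects.
#' @param transporters List of [transporter_process()] objects.
#' @param interaction An [interaction_parameters()] object or `NULL`.
#' @param metabolites Character vector of metabolite species ids whose
#'   parameter sets are carried alongside (informational; linkage is through
#'   pathway `product` fields).
#' @return An object of class `drug_parameters`.
#' @export
drug_parameters <- function(name, molecular_weight, pka_list = list(),
                            log_p, solubility = NA_real_, permeability_papp,
                            fup_healthy, fup_patient = NA_real_,
                            rbp_healthy, rbp_patient = NA_real_,
                            gfr_fraction = 1, kia_scale = 1, kir_scale = 1,
                            weibull_t50 = 45, weibull_shape = 0.92,
                            cl_additional = NULL, k_csf_p = 0,
                            k_csf_reference = c("unbound_plasma", "total_plasma"),
                            pathways = list(), transporters = list(),
                            interaction = NULL, metabolites = character()) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  .check_scalar(molecular_weight, "molecular_weight", 0, open_lower = TRUE)
  .check_scalar(log_p, "log_p")
  .check_scalar(permeability_papp, "permeability_papp", 0, open_lower = TRUE)
  .check_scalar(fup_healthy, "fup_healthy", 0, 1, open_lower = TRUE)
  if (!is.na(fup_patient)) {
    .check_scalar(fup_patient, "fup_patient", 0, 1, open_lower = TRUE)
  }
  .check_scalar(rbp_healthy, "rbp_healthy", 0, open_lower = TRUE)
  if (!is.na(rbp_patient)) {
    .check_scalar(rbp_patient, "rbp_patient", 0, open_lower = TRUE)
  }
  .check_scalar(gfr_fraction, "gfr_fraction", 0)
  .check_scalar(kia_scale, "kia_scale", 0, open_lower = TRUE)
  .check_scalar(kir_scale, "kir_scale", 0, open_lower = TRUE)
  .check_scalar(weibull_t50, "weibull_t50", 0, open_lower = TRUE)
  .check_scalar(weibull_shape, "weibull_shape", 0, open_lower = TRUE)
  .check_scalar(cl_additional, "cl_additional", 0, allow_null = TRUE)
  .check_scalar(k_csf_p, "k_csf_p", 0)
  k_csf_reference <- match.arg(k_csf_reference)
  for (p in pka_list) {
    stopifnot(is.list(p), !is.null(p$value), p$type %in% c("acid", "base"))
  }
  stopifnot(all(vapply(pathways, inherits, TRUE, "enzyme_pathway")))
  stopifnot(all(vapply(transporters, inherits, TRUE, "transporter_process")))
  if (!is.null(interaction)) {
    stopifnot(inherits(interaction, "interaction_parameters"))
  }
  structure(
    list(name = name, molecular_weight = molecular_weight,
         pka_list = pka_list, log_p = log_p, solubility = solubility,
         permeability_papp = permeability_papp,
         fup_healthy = fup_healthy, fup_patient = fup_patient,
         rbp_healthy = rbp_healthy, rbp_patient = rbp_patient,
         gfr_fraction = gfr_fraction, kia_scale = kia_scale,
         kir_scale = kir_scale, weibull_t50 = weibull_t50,
         weibull_shape = weibull_shape, cl_additional = cl_additional,
         k_csf_p = k_csf_p, k_csf_reference = k_csf_reference,
         pathways = pathways, transporters = transporters,
         interaction = interaction, metabolites = metabolites),
    class = "drug_parameters"
  )
}

#' @export
print.drug_parameters <- function(x, ...) {
  cat("<drug_parameters> ", x$name, "\n", sep = "")
  cat(sprintf("  MW %.1f g/mol, logP %.2f, Papp %.3g cm/s\n",
              x$molecular_weight, x$log_p, x$permeability_papp))
  cat(sprintf("  fup %.4g/%.4g  Rbp %.3g/%.3g (healthy/patient)\n",
              x$fup_healthy, x$fup_patient, x$rbp_healthy, x$rbp_patient))
  cat(sprintf("  %d metabolic pathway(s), %d transporter(s)\n",
              length(x$pathways), length(x$transporters)))
  invisible(x)
}

#' ALK variant with binding affinity
#'
#' @param name `"wild-type"`, `"L1196M"`, `"G1269A"` or `"G1202R"` (free text
#'   allowed).
#' @param ki Equilibrium dissociation constant against the variant, nM (> 0).
#' @param ctrough_threshold Optional efficacy-linked total plasma trough
#'   threshold, ng/mL.
#' @return An object of class `alk_variant`.
#' @export
alk_variant <- function(name, ki, ctrough_threshold = NA_real_) {
  stopifnot(is.character(name), length(name) == 1L)
  .check_scalar(ki, "ki", 0, open_lower = TRUE)
  if (!is.na(ctrough_threshold)) {
    .check_scalar(ctrough_threshold, "ctrough_threshold", 0, open_lower = TRUE)
  }
  structure(list(name = name, ki = ki,
                 ctrough_threshold = ctrough_threshold),
            class = "alk_variant")
}
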