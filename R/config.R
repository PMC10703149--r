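# Structured-text configuration layer. Drug, physiology and ALK-variant
# parameter sets are YAML key trees; the package ships the three inhibitor
# configs (plus the alectinib metabolite M4), editable placeholder
# perpetrator configs, and healthy/cancer physiology scalars under
# inst/extdata/. Units in the files follow the source tables verbatim; the
# loaders normalise to the internal h / L / umol system.

#' Path to a shipped configuration file
#'
#' @param ... Path components below `inst/extdata`, e.g.
#'   `alk_config("drugs", "crizotinib.yaml")`. With no arguments, lists the
#'   available files.
#' @return A file path, or a character vector of available configs.
#' @export
alk_config <- function(...) {
  base <- system.file("extdata", package = "alkpbpk")
  if (!nzchar(base)) stop("package data directory not found")
  parts <- c(...)
  if (!length(parts)) {
    return(list.files(base, recursive = TRUE))
  }
  p <- file.path(base, ...)
  if (!file.exists(p)) stop("no shipped config: ", file.path(...))
  p
}

#' Read a drug parameter config
#'
#' @param path YAML file path (see `alk_config()` for shipped files).
#' @return A validated [drug_parameters()] object.
#' @export
read_drug_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  required <- c("name", "molecular_weight", "log_p", "permeability_papp_cm_s",
                "fup", "rbp")
  miss <- setdiff(required, names(cfg))
  if (length(miss)) {
    stop("drug config ", basename(path), " missing fields: ",
         paste(miss, collapse = ", "))
  }
  pka <- lapply(cfg$pka %||% list(), function(p) {
    list(value = as.numeric(p$value), type = p$type)
  })
  paths <- lapply(cfg$pathways %||% list(), function(p) {
    if (!is.null(p$v_max)) {
      enzyme_pathway(p$enzyme, v_max = p$v_max, k_m = p$k_m,
                     product = p$product %||% "sink")
    } else {
      enzyme_pathway(p$enzyme, cl_int = p$cl_int,
                     cl_int_basis = p$basis %||% "per_mg_protein",
                     isef = p$isef %||% NA_real_,
                     product = p$product %||% "sink")
    }
  })
  trans <- lapply(cfg$transporters %||% list(), function(tr) {
    transporter_process(tr$transporter %||% "P-gp", cl_int = tr$cl_int,
                        k_m = tr$k_m, site = tr$site %||% "brain")
  })
  inter <- NULL
  if (!is.null(cfg$interaction)) {
    ia <- cfg$interaction
    inter <- interaction_parameters(
      ki_cyp3a4 = ia$ki_cyp3a4, kinact_cyp3a4 = ia$kinact_cyp3a4,
      emax_cyp3a4 = ia$emax_cyp3a4, ec50_cyp3a4 = ia$ec50_cyp3a4,
      ki_pgp = ia$ki_pgp)
  }
  drug_parameters(
    name = cfg$name, molecular_weight = cfg$molecular_weight,
    pka_list = pka, log_p = cfg$log_p,
    solubility = cfg$solubility_mg_ml %||% NA_real_,
    permeability_papp = cfg$permeability_papp_cm_s,
    fup_healthy = cfg$fup$healthy, fup_patient = cfg$fup$patient %||% NA_real_,
    rbp_healthy = cfg$rbp$healthy, rbp_patient = cfg$rbp$patient %||% NA_real_,
    gfr_fraction = cfg$gfr_fraction %||% 1,
    kia_scale = cfg$kia_scale %||% 1, kir_scale = cfg$kir_scale %||% 1,
    weibull_t50 = (cfg$weibull %||% list())$t50_min %||% 45,
    weibull_shape = (cfg$weibull %||% list())$shape %||% 0.92,
    cl_additional = cfg$cl_additional_l_h_kg,
    k_csf_p = cfg$k_csf_p %||% 0,
    k_csf_reference = cfg$k_csf_reference %||% "unbound_plasma",
    pathways = paths, transporters = trans, interaction = inter,
    metabolites = as.character(cfg$metabolites %||% character())
  )
}

#' Write a drug parameter config
#'
#' Inverse of [read_drug_config()]; a written file reads back into an
#' identical parameter set.
#'
#' @param drug A [drug_parameters()] object.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_drug_config <- function(drug, path) {
  stopifnot(inherits(drug, "drug_parameters"))
  cfg <- list(
    name = drug$name, molecular_weight = drug$molecular_weight,
    pka = lapply(drug$pka_list, function(p) list(value = p$value,
                                                 type = p$type)),
    log_p = drug$log_p,
    solubility_mg_ml = if (is.na(drug$solubility)) NULL else drug$solubility,
    permeability_papp_cm_s = drug$permeability_papp,
    fup = list(healthy = drug$fup_healthy,
               patient = if (is.na(drug$fup_patient)) NULL else
                 drug$fup_patient),
    rbp = list(healthy = drug$rbp_healthy,
               patient = if (is.na(drug$rbp_patient)) NULL else
                 drug$rbp_patient),
    gfr_fraction = drug$gfr_fraction,
    kia_scale = drug$kia_scale, kir_scale = drug$kir_scale,
    weibull = list(t50_min = drug$weibull_t50, shape = drug$weibull_shape),
    cl_additional_l_h_kg = drug$cl_additional,
    k_csf_p = drug$k_csf_p, k_csf_reference = drug$k_csf_reference,
    pathways = lapply(drug$pathways, function(p) {
      if (!is.null(p$v_max)) {
        list(enzyme = p$enzyme, v_max = p$v_max, k_m = p$k_m,
             product = p$product)
      } else {
        out <- list(enzyme = p$enzyme, cl_int = p$cl_int,
                    basis = p$cl_int_basis, product = p$product)
        if (!is.na(p$isef)) out$isef <- p$isef
        out
      }
    }),
    transporters = lapply(drug$transporters, function(tr) {
      list(transporter = tr$transporter, cl_int = tr$cl_int, k_m = tr$k_m,
           site = tr$site)
    }),
    interaction = if (is.null(drug$interaction)) NULL else
      Filter(Negate(is.null), unclass(drug$interaction)),
    metabolites = as.list(drug$metabolites)
  )
  cfg <- Filter(Negate(is.null), cfg)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Read a physiology config
#'
#' Scalar physiology (albumin, hematocrit, GFR, body weight, expression
#' overrides) is read from YAML and merged onto the packaged reference-human
#' organ dataset ([default_human_physiology()]).
#'
#' @param path YAML file path.
#' @return A [physiology_parameters()] object.
#' @export
read_physiology_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  phys <- default_human_physiology(body_weight = cfg$body_weight %||% 73)
  phys$population_tag <- cfg$population_tag %||% "healthy"
  phys$albumin <- cfg$albumin_g_dl %||% phys$albumin
  phys$hematocrit <- cfg$hematocrit %||% phys$hematocrit
  phys$gfr <- cfg$gfr_ml_min %||% phys$gfr
  for (ov in cfg$expression %||% list()) {
    i <- match(ov$molecule, phys$expression_table$molecule)
    if (is.na(i)) stop("unknown molecule in expression override: ", ov$molecule)
    if (!is.null(ov$reference_conc_uM)) {
      phys$expression_table$reference_conc_uM[i] <- ov$reference_conc_uM
    }
    if (!is.null(ov$rel_brain)) {
      phys$expression_table$rel_brain[i] <- ov$rel_brain
    }
  }
  for (ov in cfg$liver %||% list()) phys$liver[[names(ov)]] <- ov[[1]]
  phys
}

#' Shipped ALK variant sets
#'
#' Variant names, binding constants (Ki, nM) and efficacy-linked plasma
#' trough thresholds for each inhibitor, as tabulated.
#'
#' @param drug_name `"crizotinib"`, `"alectinib"` or `"lorlatinib"`.
#' @param path Optional custom YAML (defaults to the shipped table).
#' @return A list of [alk_variant()] objects.
#' @export
read_alk_variants <- function(drug_name, path = NULL) {
  path <- path %||% alk_config("alk-variants.yaml")
  cfg <- yaml::read_yaml(path)
  entry <- cfg[[drug_name]]
  if (is.null(entry)) stop("no variant set for drug: ", drug_name)
  lapply(entry$variants, function(v) {
    alk_variant(v$name, v$ki_nM,
                ctrough_threshold = v$ctrough_threshold_ngml %||% NA_real_)
  })
}

#' Load a shipped inhibitor with metabolites resolved
#'
#' Convenience loader: returns the drug and any shipped metabolite parameter
#' sets as a list suitable for [build_model()].
#'
#' @param drug_name `"crizotinib"`, `"alectinib"` or `"lorlatinib"`.
#' @return A list of [drug_parameters()] (parent first).
#' @export
load_drug_set <- function(drug_name) {
  d <- read_drug_config(alk_config("drugs", paste0(drug_name, ".yaml")))
  out <- list(d)
  for (mname in d$metabolites) {
    out[[length(out) + 1]] <-
      read_drug_config(alk_config("drugs", paste0(mname, ".yaml")))
  }
  out
}
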