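#' Physiology parameter set
#'
#' Organ volumes, blood flows, sub-compartment fractions, tissue composition
#' for partitioning, plasma protein level, hematocrit, GFR and the hepatic
#' protein-expression table. Construct a reference set with
#' [default_human_physiology()] and derive a cancer set with
#' [apply_cancer_physiology()].
#'
#' @param population_tag `"healthy"` or `"cancer"`.
#' @param albumin Plasma albumin, g/dl (> 0).
#' @param hematocrit Fraction in (0, 1).
#' @param gfr Glomerular filtration rate, mL/min (> 0).
#' @param body_weight kg (> 0).
#' @param organs Data frame with one row per organ (see
#'   [default_human_physiology()] for required columns).
#' @param expression_table Data frame with columns `molecule`,
#'   `reference_conc_uM` (uM per L liver tissue), `turnover_half_life_h`,
#'   `rel_brain` (expression at the blood-brain barrier relative to the liver
#'   reference).
#' @param blood Named list: `v_venous`, `v_arterial` (L), `ph_plasma`,
#'   `ph_intracellular`, `ph_blood_cells`, blood-cell composition
#'   (`bc_f_iw`, `bc_f_nl`, `bc_f_np`, `bc_ap`), plasma lipid fractions
#'   (`plasma_f_nl`, `plasma_f_np`).
#' @param liver Named list: `mass_g`, `volume_l`,
#'   `microsomal_protein_mg_per_g` (the protein-abundance scalar bridging
#'   per-mg-protein intrinsic clearances to whole-liver values).
#' @return An object of class `physiology_parameters`.
#' @export
physiology_parameters <- function(population_tag = c("healthy", "cancer"),
                                  albumin, hematocrit, gfr, body_weight,
                                  organs, expression_table, blood, liver) {
  population_tag <- match.arg(population_tag)
  .check_scalar(albumin, "albumin", 0, open_lower = TRUE)
  .check_scalar(hematocrit, "hematocrit", 0, 1,
                open_lower = TRUE, open_upper = TRUE)
  .check_scalar(gfr, "gfr", 0, open_lower = TRUE)
  .check_scalar(body_weight, "body_weight", 0, open_lower = TRUE)
  need <- c("organ", "volume_l", "flow_lph", "f_vas", "f_int", "f_cell",
            "f_ew", "f_iw", "f_nl", "f_np", "ap_mg_g", "pr_ratio",
            "sa_factor", "barrier_factor")
  miss <- setdiff(need, names(organs))
  if (length(miss)) stop("organs table missing columns: ",
                         paste(miss, collapse = ", "))
  if (any(organs$volume_l <= 0) || any(organs$flow_lph <= 0)) {
    stop("all organ volumes and flows must be > 0")
  }
  frac_sum <- organs$f_vas + organs$f_int + organs$f_cell
  if (any(abs(frac_sum - 1) > 1e-6)) {
    stop("sub-compartment fractions must sum to 1 per organ")
  }
  stopifnot(all(c("molecule", "reference_conc_uM", "turnover_half_life_h",
                  "rel_brain") %in% names(expression_table)))
  if (any(expression_table$reference_conc_uM < 0)) {
    stop("reference concentrations must be >= 0")
  }
  structure(
    list(population_tag = population_tag, albumin = albumin,
         hematocrit = hematocrit, gfr = gfr, body_weight = body_weight,
         organs = organs, expression_table = expression_table,
         blood = blood, liver = liver),
    class = "physiology_parameters"
  )
}

#' @export
print.physiology_parameters <- function(x, ...) {
  cat("<physiology_parameters> ", x$population_tag, "\n", sep = "")
  cat(sprintf("  albumin %.2f g/dl, Hct %.2f, GFR %.0f mL/min, BW %.0f kg\n",
              x$albumin, x$hematocrit, x$gfr, x$body_weight))
  cat(sprintf("  %d organs, cardiac output %.0f L/h\n",
              nrow(x$organs), sum(x$organs$flow_lph[x$organs$organ != "lung"])))
  invisible(x)
}

#' Reference human physiology
#'
#' A packaged reference-human dataset (73 kg adult): organ volumes and blood
#' flows, sub-compartment volume fractions, tissue composition for
#' tissue-partitioning calculations (water/lipid/phospholipid fractions,
#' acidic phospholipid content, tissue-to-plasma albumin ratio), vascular
#' surface-area parameters, and the hepatic enzyme/transporter expression
#' table. All values are overridable through the returned object or a
#' physiology config file.
#'
#' `flow_lph` is the systemic blood inflow per organ; for the liver it is the
#' hepatic-artery flow only (portal inflow arrives through gut and spleen),
#' and the lung carries total cardiac output. `barrier_factor` scales the
#' vascular exchange surface; the small brain value encodes blood-brain
#' barrier tightness.
#'
#' @param body_weight Body weight in kg; organ volumes scale linearly and
#'   flows/GFR with the 3/4 power relative to the 73 kg reference.
#' @return A [physiology_parameters()] object tagged `"healthy"`.
#' @export
default_human_physiology <- function(body_weight = 73) {
  w <- body_weight / 73
  organs <- data.frame(
    organ   = c("lung", "brain", "heart", "kidney", "liver", "gut",
                "spleen", "muscle", "adipose", "skin", "bone", "rest"),
    volume_l = c(0.55, 1.45, 0.33, 0.31, 1.65, 1.10,
                 0.15, 29.0, 13.0, 3.30, 10.0, 3.50) * w,
    # systemic inflow; lung = cardiac output (sum of the others)
    flow_lph = c(337.4, 46, 14, 66, 19, 58,
                 4.6, 45, 19, 17, 12, 36.8) * w^0.75,
    f_vas  = c(0.11, 0.030, 0.10, 0.11, 0.11, 0.07,
               0.22, 0.040, 0.020, 0.050, 0.040, 0.060),
    f_int  = c(0.19, 0.180, 0.10, 0.20, 0.16, 0.28,
               0.15, 0.120, 0.140, 0.300, 0.100, 0.150),
    f_cell = c(0.70, 0.790, 0.80, 0.69, 0.73, 0.65,
               0.63, 0.840, 0.840, 0.650, 0.860, 0.790),
    # tissue composition (fraction of tissue mass): extracellular water,
    # intracellular water, neutral lipid, neutral phospholipid; acidic
    # phospholipid mg/g; tissue-to-plasma albumin-equivalent ratio
    f_ew   = c(0.336, 0.162, 0.320, 0.273, 0.161, 0.282,
               0.207, 0.118, 0.135, 0.382, 0.100, 0.250),
    f_iw   = c(0.446, 0.620, 0.456, 0.483, 0.573, 0.475,
               0.579, 0.630, 0.017, 0.291, 0.346, 0.450),
    f_nl   = c(0.022, 0.039, 0.014, 0.012, 0.014, 0.038,
               0.0077, 0.010, 0.853, 0.060, 0.017, 0.040),
    f_np   = c(0.0128, 0.0015, 0.0111, 0.0242, 0.0240, 0.0125,
               0.0113, 0.0072, 0.0016, 0.0044, 0.0017, 0.0080),
    ap_mg_g = c(3.91, 0.40, 2.25, 5.03, 4.56, 2.41,
                3.18, 1.53, 0.40, 1.32, 0.67, 2.00),
    pr_ratio = c(0.212, 0.048, 0.157, 0.130, 0.086, 0.158,
                 0.097, 0.064, 0.049, 0.277, 0.100, 0.100),
    # vascular exchange surface, cm^2 per L tissue (fenestrated/sinusoidal
    # endothelia in kidney, liver, spleen and gut mucosa exchange much
    # faster than continuous capillaries), and barrier tightness
    sa_factor = c(1e7, 1e7, 1e7, 1e9, 1e8, 1e8,
                  1e9, 1e7, 1e7, 1e7, 1e7, 1e7),
    barrier_factor = c(1, 2e-4, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1),
    stringsAsFactors = FALSE
  )
  expression_table <- data.frame(
    molecule = c("CYP3A4", "CYP3A5", "CYP2C8", "CYP2C19",
                 "UGT1A3", "UGT1A4", "P-gp"),
    reference_conc_uM = c(4.32, 0.04, 2.56, 0.76, 0.53, 0.25, 0.68),
    turnover_half_life_h = c(36, NA, NA, NA, NA, NA, NA),
    rel_brain = c(0, 0, 0, 0, 0, 0, 1.25),
    stringsAsFactors = FALSE
  )
  blood <- list(
    v_venous = 3.9 * w, v_arterial = 1.8 * w,
    ph_plasma = 7.4, ph_intracellular = 7.0, ph_blood_cells = 7.22,
    bc_f_iw = 0.603, bc_f_nl = 0.0017, bc_f_np = 0.0029, bc_ap = 0.57,
    plasma_f_nl = 0.0023, plasma_f_np = 0.0013
  )
  liver <- list(mass_g = 1800 * w, volume_l = 1.65 * w,
                microsomal_protein_mg_per_g = 45)
  physiology_parameters(
    population_tag = "healthy", albumin = 4.5, hematocrit = 0.43,
    gfr = 120 * w^0.75, body_weight = body_weight, organs = organs,
    expression_table = expression_table, blood = blood, liver = liver
  )
}

#' Switch a healthy physiology (and paired drug) to the cancer state
#'
#' Applies the disease adjustments: hepatic CYP3A4 reference concentration
#' 4.32 -> 3.02 uM and CYP2C19 0.76 -> 0.51 uM (scaled proportionally if the
#' healthy set was customised), albumin 4.5 -> 3.1 g/dl, hematocrit
#' 0.43 -> 0.33, doubled P-gp expression at the blood-brain barrier for drugs
#' carrying a brain P-gp efflux process, and patient unbound fraction /
#' blood-to-plasma ratio derived with [scale_fup_to_patient()],
#' [compute_kpu_bc()] and [scale_rbp_to_patient()] (unrounded).
#'
#' @param healthy A [physiology_parameters()] object tagged `"healthy"`.
#' @param drug A [drug_parameters()] object.
#' @param albumin_patient Patient albumin, g/dl.
#' @param hematocrit_patient Patient hematocrit.
#' @param cyp3a4_factor,cyp2c19_factor Expression down-regulation factors.
#' @param pgp_brain_factor Fold-change of brain-barrier P-gp, applied only
#'   when `drug` has a brain P-gp efflux process.
#' @return `list(physiology = , drug = )` with the cancer-state copies.
#' @export
apply_cancer_physiology <- function(healthy, drug,
                                    albumin_patient = 3.1,
                                    hematocrit_patient = 0.33,
                                    cyp3a4_factor = 3.02 / 4.32,
                                    cyp2c19_factor = 0.51 / 0.76,
                                    pgp_brain_factor = 2) {
  stopifnot(inherits(healthy, "physiology_parameters"),
            inherits(drug, "drug_parameters"))
  if (healthy$population_tag != "healthy") {
    stop("input physiology is already tagged '", healthy$population_tag, "'")
  }
  phys <- healthy
  phys$population_tag <- "cancer"
  et <- phys$expression_table
  et$reference_conc_uM[et$molecule == "CYP3A4"] <-
    et$reference_conc_uM[et$molecule == "CYP3A4"] * cyp3a4_factor
  et$reference_conc_uM[et$molecule == "CYP2C19"] <-
    et$reference_conc_uM[et$molecule == "CYP2C19"] * cyp2c19_factor
  has_brain_pgp <- any(vapply(
    drug$transporters,
    function(tr) tr$transporter == "P-gp" && tr$site == "brain", TRUE
  ))
  if (has_brain_pgp) {
    et$rel_brain[et$molecule == "P-gp"] <-
      et$rel_brain[et$molecule == "P-gp"] * pgp_brain_factor
  }
  phys$expression_table <- et
  fup_prime <- scale_fup_to_patient(drug$fup_healthy, healthy$albumin,
                                    albumin_patient)
  kpu_bc <- compute_kpu_bc(drug$fup_healthy, drug$rbp_healthy,
                           healthy$hematocrit)
  rbp_prime <- scale_rbp_to_patient(fup_prime, kpu_bc, hematocrit_patient)
  phys$albumin <- albumin_patient
  phys$hematocrit <- hematocrit_patient
  drug$fup_patient <- fup_prime
  drug$rbp_patient <- rbp_prime
  list(physiology = phys, drug = drug)
}

# internal: population-appropriate fup / rbp for a drug
.fup_for <- function(drug, physiology) {
  if (physiology$population_tag == "cancer" && !is.na(drug$fup_patient)) {
    drug$fup_patient
  } else {
    drug$fup_healthy
  }
}
.rbp_for <- function(drug, physiology) {
  if (physiology$population_tag == "cancer" && !is.na(drug$rbp_patient)) {
    drug$rbp_patient
  } else {
    drug$rbp_healthy
  }
}
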