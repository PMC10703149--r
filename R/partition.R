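# Tissue-to-plasma partitioning by the Rodgers-Rowland composition scheme.
#
# Moderate-to-strong bases (any basic pKa >= 7) partition into tissue through
# ionic association with acidic phospholipids, with the association constant
# back-calculated from the measured blood-cell affinity; neutrals, acids and
# weak bases bind extracellular proteins, scaled from the measured plasma
# unbound fraction. Lipid partitioning uses octanol (bases) or a
# vegetable-oil conversion (neutral-lipid term of the protein class).

# ionization factor X = total/neutral at a given pH
.ionization_x <- function(pka_list, ph) {
  x <- 1
  bases <- sort(vapply(Filter(function(p) p$type == "base", pka_list),
                       `[[`, 0, "value"), decreasing = TRUE)
  acids <- vapply(Filter(function(p) p$type == "acid", pka_list),
                  `[[`, 0, "value")
  if (length(bases) >= 1) x <- x + 10^(bases[1] - ph)
  if (length(bases) >= 2) x <- x + 10^(bases[1] + bases[2] - 2 * ph)
  for (pk in acids) x <- x + 10^(ph - pk)
  x
}

.is_strong_base <- function(pka_list) {
  any(vapply(pka_list, function(p) p$type == "base" && p$value >= 7, TRUE))
}

#' Tissue-to-plasma partition coefficients (Rodgers-Rowland)
#'
#' Computes, per organ, the equilibrium intracellular and interstitial
#' partition coefficients relative to unbound plasma, applying the drug's
#' `kia_scale` (intracellular) and `kir_scale` (interstitial) multipliers.
#'
#' @param drug A [drug_parameters()] object.
#' @param physiology A [physiology_parameters()] object (supplies tissue
#'   composition, pH values, hematocrit and the population-appropriate
#'   unbound fraction / blood-to-plasma ratio).
#' @return A data frame with one row per organ: `organ`, `kpu_cell`
#'   (total-intracellular to unbound-plasma, `kia_scale` applied), `kpu_int`
#'   (total-interstitial to unbound-plasma, `kir_scale` applied), `trap_cell`
#'   (intracellular-water to plasma-water ratio of the unbound drug, from the
#'   pH gradient), and `kp_total` (whole-tissue to total-plasma coefficient,
#'   informational).
#' @export
rodgers_rowland_partition <- function(drug, physiology) {
  stopifnot(inherits(drug, "drug_parameters"),
            inherits(physiology, "physiology_parameters"))
  org <- physiology$organs
  if (is.null(org) || !nrow(org)) stop("physiology has no tissue composition")
  bl <- physiology$blood
  fup <- .fup_for(drug, physiology)
  rbp <- .rbp_for(drug, physiology)
  hct <- physiology$hematocrit
  p_oct <- 10^drug$log_p
  x_p  <- .ionization_x(drug$pka_list, bl$ph_plasma)
  x_iw <- .ionization_x(drug$pka_list, bl$ph_intracellular)
  x_bc <- .ionization_x(drug$pka_list, bl$ph_blood_cells)
  trap <- x_iw / x_p
  lipid <- function(f_nl, f_np, p_nl) (p_nl * f_nl + (0.3 * p_oct + 0.7) * f_np) / x_p

  if (.is_strong_base(drug$pka_list)) {
    kpu_bc <- compute_kpu_bc(fup, rbp, hct)
    ka_ap <- (kpu_bc - (x_bc / x_p) * bl$bc_f_iw -
                lipid(bl$bc_f_nl, bl$bc_f_np, p_oct)) *
      x_p / ((x_bc - 1) * bl$bc_ap)
    if (!is.finite(ka_ap) || ka_ap < 0) ka_ap <- 0
    kpu_cell_raw <- (trap * org$f_iw +
      (ka_ap * org$ap_mg_g * (x_iw - 1)) / x_p +
      lipid(org$f_nl, org$f_np, p_oct)) / pmax(org$f_cell, 1e-6)
  } else {
    p_vo <- 10^(1.115 * drug$log_p - 1.35)
    ka_pr <- max(0, 1 / fup - 1 - lipid(bl$plasma_f_nl, bl$plasma_f_np, p_vo))
    kpu_cell_raw <- (trap * org$f_iw +
      lipid(org$f_nl, org$f_np, p_vo) + ka_pr * org$pr_ratio) /
      pmax(org$f_cell, 1e-6)
  }
  kpu_cell <- drug$kia_scale * pmax(kpu_cell_raw, trap * 1e-3)
  kpu_int <- drug$kir_scale * (1 + (1 / fup - 1) * org$pr_ratio)
  kp_total <- fup * (org$f_vas * rbp / fup +
                       org$f_int * kpu_int + org$f_cell * kpu_cell)
  data.frame(organ = org$organ, kpu_cell = kpu_cell, kpu_int = kpu_int,
             trap_cell = trap, kp_total = kp_total,
             stringsAsFactors = FALSE)
}
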