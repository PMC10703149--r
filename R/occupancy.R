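#' Map a plasma concentration series into CSF
#'
#' Cerebrospinal-fluid exposure is obtained by scaling the venous plasma
#' concentration with the unbound fraction and the CSF-to-plasma ratio
#' `K_CSF,P`. Literature ratios are heterogeneous in their reference
#' concentration, so the provenance flag decides the arithmetic:
#' \itemize{
#'   \item `reference = "unbound"`: `C_CSF = C_p,total * fup * K` (the ratio
#'     tracks unbound plasma, as for alectinib 0.79 and lorlatinib 0.77);
#'   \item `reference = "total"`: `C_CSF = C_p,total * K` (the ratio already
#'     relates CSF to total plasma, as for crizotinib 0.0026).
#' }
#' The result is an unbound CSF concentration either way.
#'
#' @param plasma_total Total plasma concentration series (any unit).
#' @param fup Population-appropriate unbound plasma fraction.
#' @param k_csf_p CSF-to-plasma ratio (>= 0).
#' @param reference `"unbound"` or `"total"` (which plasma concentration the
#'   ratio refers to).
#' @return Unbound CSF concentration series, same unit as the input.
#' @export
#' @examples
#' # lorlatinib: unbound plasma trough 160 nM, K = 0.77 -> 123 nM in CSF
#' csf_concentration(160 / 0.43, 0.43, 0.77, "unbound")
csf_concentration <- function(plasma_total, fup, k_csf_p,
                              reference = c("unbound", "total")) {
  reference <- match.arg(reference)
  .check_scalar(k_csf_p, "k_csf_p", 0)
  .check_scalar(fup, "fup", 0, 1, open_lower = TRUE)
  stopifnot(is.numeric(plasma_total))
  if (reference == "unbound") plasma_total * fup * k_csf_p
  else plasma_total * k_csf_p
}

#' Equilibrium ALK occupancy
#'
#' Percent target engagement from the unbound inhibitor concentration and the
#' binding constant: `AO = 100 * I_free / (Ki + I_free)`. Strictly increasing
#' in `I_free`, strictly decreasing in `Ki`, bounded in \[0, 100).
#'
#' @param i_free Unbound concentration at the target site, nM (>= 0,
#'   vectorised).
#' @param ki Equilibrium dissociation constant, nM (> 0).
#' @return Occupancy, percent.
#' @export
#' @examples
#' occupancy(78.2, 10)  # ~88.7
occupancy <- function(i_free, ki) {
  if (!is.numeric(ki) || length(ki) != 1L || !is.finite(ki) || ki <= 0) {
    stop("'ki' must be a single positive number (nM)")
  }
  stopifnot(is.numeric(i_free), all(i_free >= 0))
  100 * i_free / (ki + i_free)
}

#' Assess a dosing regimen against trough and occupancy thresholds
#'
#' Takes per-subject steady-state total plasma trough concentrations from a
#' population simulation, derives unbound plasma and CSF troughs, evaluates
#' the minimal ALK occupancy per variant (occupancy at trough, since
#' occupancy is a monotone transform of concentration), and summarises with
#' geometric means and log-normal confidence intervals. A regimen passes for
#' a variant when the geometric-mean total plasma trough meets the variant's
#' trough threshold (when one is defined) and the geometric-mean occupancy
#' exceeds `ao_threshold` at the requested site.
#'
#' @param ctrough_total_ngml Numeric vector of per-subject steady-state total
#'   plasma trough concentrations, ng/mL (> 0).
#' @param drug A [drug_parameters()] object (supplies MW, patient unbound
#'   fraction, `k_csf_p` and its provenance flag).
#' @param variants List of [alk_variant()] objects.
#' @param ao_threshold Occupancy threshold, percent (default 75).
#' @param site `"plasma"` or `"csf"`: site whose occupancy gates the
#'   pass/fail call.
#' @param ci_level Confidence level for the log-normal CI (default 0.90).
#' @return An object of class `regimen_assessment`: a data frame with one row
#'   per variant and site (`plasma`, `csf`): unbound trough (nM, geometric
#'   mean + CI), minimal occupancy (%, geometric mean + CI), and the
#'   pass/fail flags.
#' @export
assess_regimen <- function(ctrough_total_ngml, drug, variants,
                           ao_threshold = 75, site = c("plasma", "csf"),
                           ci_level = 0.90) {
  site <- match.arg(site)
  stopifnot(inherits(drug, "drug_parameters"), length(variants) >= 1,
            all(vapply(variants, inherits, TRUE, "alk_variant")))
  if (any(!is.finite(ctrough_total_ngml)) || any(ctrough_total_ngml <= 0)) {
    stop("trough concentrations must be positive")
  }
  fup <- if (!is.na(drug$fup_patient)) drug$fup_patient else drug$fup_healthy
  u_plasma_nM <- unit_convert(ctrough_total_ngml * fup, drug$molecular_weight,
                              "ngml_to_nM")
  total_nM <- unit_convert(ctrough_total_ngml, drug$molecular_weight,
                           "ngml_to_nM")
  u_csf_nM <- csf_concentration(
    total_nM, fup, drug$k_csf_p,
    reference = if (drug$k_csf_reference == "total_plasma") "total"
                else "unbound")
  gm_total_ngml <- summarize_geomean(ctrough_total_ngml, ci_level)$geo_mean
  rows <- list()
  for (v in variants) {
    for (st in c("plasma", "csf")) {
      u <- if (st == "plasma") u_plasma_nM else u_csf_nM
      if (any(u <= 0)) stop("non-positive unbound trough for site ", st)
      s_u <- summarize_geomean(u, ci_level)
      ao <- occupancy(u, v$ki)
      s_ao <- summarize_geomean(ao, ci_level)
      pass_ct <- if (is.na(v$ctrough_threshold)) NA else
        gm_total_ngml >= v$ctrough_threshold * (1 - 1e-9)
      pass_ao <- s_ao$geo_mean > ao_threshold
      rows[[length(rows) + 1]] <- data.frame(
        variant = v$name, ki_nM = v$ki, site = st,
        ctrough_unbound_nM = s_u$geo_mean,
        ctrough_lo = s_u$ci_lower, ctrough_hi = s_u$ci_upper,
        min_ao_pct = s_ao$geo_mean,
        ao_lo = s_ao$ci_lower, ao_hi = s_ao$ci_upper,
        ctrough_threshold_ngml = v$ctrough_threshold,
        pass_ctrough = pass_ct, pass_ao = pass_ao,
        pass = identical(pass_ct, FALSE) == FALSE & pass_ao,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  # the gating site decides the overall call
  out$gating_site <- site
  attr(out, "gm_total_plasma_ngml") <- gm_total_ngml
  attr(out, "ao_threshold") <- ao_threshold
  class(out) <- c("regimen_assessment", class(out))
  out
}

#' @export
print.regimen_assessment <- function(x, ...) {
  cat("<regimen_assessment> gm total plasma Ctrough",
      sprintf("%.1f ng/mL;", attr(x, "gm_total_plasma_ngml")),
      "AO threshold", attr(x, "ao_threshold"), "%\n")
  print.data.frame(x, digits = 3)
  invisible(x)
}
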