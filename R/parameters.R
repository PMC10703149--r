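#' Scale the unbound plasma fraction to a patient albumin level
#'
#' Cancer patients have reduced plasma albumin; the bound fraction scales with
#' the albumin concentration while the free drug equilibrium is preserved:
#' \deqn{f_{up}' = \frac{1}{1 + \frac{1-f_{up}}{f_{up}} \cdot [P]'/[P]}}
#'
#' @param fup Unbound fraction in plasma of the reference (healthy) population,
#'   in (0, 1].
#' @param albumin_healthy,albumin_patient Plasma albumin, g/dl (> 0).
#' @return Patient unbound fraction, in (0, 1].
#' @export
#' @examples
#' scale_fup_to_patient(0.093, 4.5, 3.1)  # ~0.13
scale_fup_to_patient <- function(fup, albumin_healthy, albumin_patient) {
  .check_scalar(fup, "fup", 0, 1, open_lower = TRUE)
  .check_scalar(albumin_healthy, "albumin_healthy", 0, open_lower = TRUE)
  .check_scalar(albumin_patient, "albumin_patient", 0, open_lower = TRUE)
  1 / (1 + (1 - fup) / fup * (albumin_patient / albumin_healthy))
}

#' Blood-cell partition affinity from measured blood-to-plasma ratio
#'
#' The unbound affinity of blood cells for a drug, back-calculated from the
#' measured blood-to-plasma ratio, hematocrit and unbound plasma fraction:
#' \deqn{K_{puBC} = \frac{Hct - 1 + R_{bp}}{Hct \cdot f_{up}}}
#' A negative numerator (drug excluded from blood cells beyond what a zero
#' cell concentration can explain) is physically impossible and raises an
#' error rather than returning a negative affinity.
#'
#' @param fup Unbound fraction in plasma (> 0).
#' @param rbp Blood-to-plasma concentration ratio (> 0).
#' @param hct Hematocrit, in (0, 1).
#' @return Unitless blood-cell-to-unbound-plasma affinity.
#' @export
compute_kpu_bc <- function(fup, rbp, hct) {
  .check_scalar(fup, "fup", 0, 1, open_lower = TRUE)
  .check_scalar(rbp, "rbp", 0, open_lower = TRUE)
  .check_scalar(hct, "hct", 0, 1, open_lower = TRUE, open_upper = TRUE)
  num <- hct - 1 + rbp
  if (num < 0) {
    stop("Hct - 1 + Rbp < 0: blood-cell exclusion beyond physical limit; ",
         "check fup/Rbp/Hct inputs")
  }
  num / (hct * fup)
}

#' Scale the blood-to-plasma ratio to a patient hematocrit
#'
#' Given the blood-cell affinity (assumed disease-invariant) and the patient
#' unbound fraction and hematocrit:
#' \deqn{R_{bp}' = 1 + Hct' (f_{up}' K_{puBC} - 1)}
#' Use the unrounded patient \eqn{f_{up}'} from [scale_fup_to_patient()].
#'
#' @param fup_patient Patient unbound plasma fraction (> 0).
#' @param kpu_bc Blood-cell affinity from [compute_kpu_bc()] (> 0).
#' @param hct_patient Patient hematocrit, in (0, 1).
#' @return Patient blood-to-plasma ratio.
#' @export
scale_rbp_to_patient <- function(fup_patient, kpu_bc, hct_patient) {
  .check_scalar(fup_patient, "fup_patient", 0, 1, open_lower = TRUE)
  .check_scalar(kpu_bc, "kpu_bc", 0, open_lower = TRUE)
  .check_scalar(hct_patient, "hct_patient", 0, 1,
                open_lower = TRUE, open_upper = TRUE)
  1 + hct_patient * (fup_patient * kpu_bc - 1)
}

# ISEF defaults: intersystem extrapolation factors scaling recombinant-enzyme
# velocities to liver-microsome-equivalent intrinsic clearance.
.isef_defaults <- c(
  CYP3A4 = 0.21, CYP3A5 = 0.12, CYP2C8 = 1.41, CYP2C19 = 0.25,
  UGT1A3 = 0.077, UGT1A4 = 0.077
)

#' ISEF-scaled intrinsic clearance
#'
#' Scales a recombinant-enzyme metabolic velocity to liver-equivalent intrinsic
#' clearance: `CLint = MV * ISEF`. When `isef` is missing, the packaged default
#' for the enzyme is used (0.21 CYP3A4, 0.12 CYP3A5, 1.41 CYP2C8, 0.25 CYP2C19,
#' 0.077 UGT1A3/1A4).
#'
#' @param mv Metabolic velocity, e.g. uL/min/pmol enzyme (>= 0).
#' @param isef Intersystem extrapolation factor (> 0), or `NULL` to default by
#'   `enzyme`.
#' @param enzyme Enzyme name used to look up the default ISEF when `isef` is
#'   `NULL`.
#' @return Intrinsic clearance on the same per-enzyme basis as `mv`.
#' @export
isef_scaled_clint <- function(mv, isef = NULL, enzyme = NULL) {
  .check_scalar(mv, "mv", 0)
  if (is.null(isef)) {
    if (is.null(enzyme) || !enzyme %in% names(.isef_defaults)) {
      stop("no default ISEF for enzyme ",
           if (is.null(enzyme)) "<missing>" else enzyme)
    }
    isef <- .isef_defaults[[enzyme]]
  }
  .check_scalar(isef, "isef", 0, open_lower = TRUE)
  mv * isef
}

#' UGT reference concentration in liver
#'
#' Converts a UGT abundance per mg microsomal protein into a liver reference
#' concentration (uM per L liver tissue):
#' `abundance * protein_per_g_liver * liver_mass / liver_volume`, pmol -> umol.
#'
#' @param abundance pmol/mg microsomal protein (>= 0).
#' @param protein_per_g_liver mg microsomal protein per g liver (default 45).
#' @param liver_mass Liver mass, g (default 1800).
#' @param liver_volume Liver volume, L (default 1.65).
#' @return Reference concentration, uM per L liver tissue.
#' @export
ugt_reference_concentration <- function(abundance, protein_per_g_liver = 45,
                                        liver_mass = 1800, liver_volume = 1.65) {
  .check_scalar(abundance, "abundance", 0)
  .check_scalar(protein_per_g_liver, "protein_per_g_liver", 0, open_lower = TRUE)
  .check_scalar(liver_mass, "liver_mass", 0, open_lower = TRUE)
  .check_scalar(liver_volume, "liver_volume", 0, open_lower = TRUE)
  # pmol/mg * mg/g * g = pmol; /1e6 -> umol; / L -> uM
  abundance * protein_per_g_liver * liver_mass / liver_volume / 1e6
}

#' P-gp reference concentration in liver
#'
#' P-glycoprotein abundance is measured in intestinal tissue; the liver
#' reference concentration is obtained from the intestinal abundance, the
#' intestine mass and the liver-to-intestine relative expression ratio:
#' `abundance * intestine_mass * ratio / liver_volume`, pmol -> umol. The
#' packaged organ-size defaults reproduce the model's recorded liver P-gp
#' reference concentration of 0.68 uM.
#'
#' @param abundance_intestine pmol/mg tissue (>= 0).
#' @param intestine_mass Intestinal tract mass, g (default 1252).
#' @param liver_to_intestine_ratio Relative expression ratio (default 0.56).
#' @param liver_volume Liver volume, L (default 1.65).
#' @return Reference concentration, uM per L liver tissue.
#' @export
pgp_reference_concentration <- function(abundance_intestine,
                                        intestine_mass = 1252,
                                        liver_to_intestine_ratio = 0.56,
                                        liver_volume = 1.65) {
  .check_scalar(abundance_intestine, "abundance_intestine", 0)
  .check_scalar(intestine_mass, "intestine_mass", 0, open_lower = TRUE)
  .check_scalar(liver_to_intestine_ratio, "liver_to_intestine_ratio", 0,
                open_lower = TRUE)
  .check_scalar(liver_volume, "liver_volume", 0, open_lower = TRUE)
  # pmol/mg tissue * g * 1000 mg/g = pmol; /1e6 -> umol; / L -> uM
  abundance_intestine * intestine_mass * 1000 * liver_to_intestine_ratio /
    liver_volume / 1e6
}

#' Cheng-Prusoff correction of an IC50 to a Ki
#'
#' For a competitive inhibitor measured at substrate concentration `[S]`:
#' `Ki = IC50 / (1 + [S]/Km)`. Kinase-assay IC50 values determined at the
#' Km level of ATP halve: `Ki = IC50 / 2`.
#'
#' @param ic50 IC50, nM (> 0).
#' @param substrate_over_km `[S]/Km` ratio of the assay (>= 0, default 1).
#' @return Ki in the same units as `ic50`.
#' @export
cheng_prusoff_ki <- function(ic50, substrate_over_km = 1) {
  .check_scalar(ic50, "ic50", 0, open_lower = TRUE)
  .check_scalar(substrate_over_km, "substrate_over_km", 0)
  ic50 / (1 + substrate_over_km)
}
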