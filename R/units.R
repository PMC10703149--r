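#' Convert concentrations between ng/mL and nM
#'
#' Mass and molar concentration interconversion using the molecular weight.
#' `nM = 1000 * (ng/mL) / MW` with MW in g/mol.
#'
#' @param conc Numeric vector of concentrations.
#' @param mw Molecular weight in g/mol (> 0).
#' @param direction `"ngml_to_nM"` or `"nM_to_ngml"`.
#' @return Numeric vector of converted concentrations.
#' @export
#' @examples
#' unit_convert(450.3, 450.3, "ngml_to_nM")  # 1000 nM
unit_convert <- function(conc, mw, direction = c("ngml_to_nM", "nM_to_ngml")) {
  direction <- match.arg(direction)
  if (!is.numeric(mw) || length(mw) != 1L || !is.finite(mw) || mw <= 0) {
    stop("'mw' must be a single positive number (g/mol)")
  }
  stopifnot(is.numeric(conc))
  if (direction == "ngml_to_nM") 1000 * conc / mw else conc * mw / 1000
}

#' Round half away from zero to a fixed number of decimals
#'
#' Printed tables round half up (0.125 -> 0.13); base `round()` rounds half to
#' even. Used when comparing computed quantities with values printed at a fixed
#' precision.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# internal: ng/mL -> uM
.ngml_to_uM <- function(conc, mw) conc / mw
# internal: uM -> ng/mL
.uM_to_ngml <- function(conc, mw) conc * mw

# internal: assert scalar in open/closed range
.check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                          open_lower = FALSE, open_upper = FALSE,
                          allow_null = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(invisible(TRUE))
    stop(sprintf("'%s' is required", name))
  }
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name))
  }
  lo_ok <- if (open_lower) x > lower else x >= lower
  hi_ok <- if (open_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    stop(sprintf(
      "'%s' = %g outside %s%g, %g%s", name, x,
      if (open_lower) "(" else "[", lower, upper, if (open_upper) ")" else "]"
    ))
  }
  invisible(TRUE)
}
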