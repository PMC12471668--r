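#' Physical constants used by the TST permeability equations
#'
#' Returns the constant set used throughout the package, in the unit
#' conventions of the permeability literature: the gas constant both in SI and
#' in kcal/(mol K), the Avogadro number, and the molar mass and molar volume
#' of water.
#'
#' @param v_W Molar volume of water in cm^3/mol. The default (18.0153, the
#'   25 degC value) is held fixed across the 5-25 degC range studied here; the
#'   variation over that range is below 0.2 percent, smaller than the
#'   statistical uncertainty of any quantity it enters.
#' @return A list of class `physical_constants` with elements `R_J`
#'   (J mol^-1 K^-1), `R_kcal` (kcal mol^-1 K^-1), `N_A` (mol^-1), `m_W`
#'   (g/mol), `v_W` (cm^3/mol), and `R_internal` (gas constant in the internal
#'   g/mol, Angstrom, ps unit system).
#' @examples
#' physical_constants()$R_kcal
#' @export
physical_constants <- function(v_W = 18.0153) {
  stopifnot(is.numeric(v_W), v_W > 0)
  structure(
    list(
      R_J        = 8.314462618,
      R_kcal     = 1.987204e-3,
      N_A        = 6.02214076e23,
      m_W        = 18.01528,
      v_W        = v_W,
      R_internal = 0.8314462618,
      kcal_internal = 418.4
    ),
    class = "physical_constants"
  )
}

#' @export
print.physical_constants <- function(x, ...) {
  cat("Physical constants:\n")
  cat(sprintf("  R    = %.9f J/(mol K) = %.6e kcal/(mol K)\n", x$R_J, x$R_kcal))
  cat(sprintf("  N_A  = %.8e /mol\n", x$N_A))
  cat(sprintf("  m_W  = %.5f g/mol\n", x$m_W))
  cat(sprintf("  v_W  = %.4f cm^3/mol\n", x$v_W))
  invisible(x)
}
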