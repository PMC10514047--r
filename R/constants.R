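# Physical constants, CODATA 2018, converted once into package units
# (nm, ps, amu, kJ/mol, K).  Single source of truth for the whole package.
.ct <- list(
  kB   = 1.380649e-23 * 6.02214076e23 / 1000,        # kJ mol^-1 K^-1
  R    = 8.314462618,                                # J mol^-1 K^-1
  NA_  = 6.02214076e23,                              # mol^-1
  # Planck constant in kJ mol^-1 ps: J s * (NA/1000) * 1e12
  h    = 6.62607015e-34 * 6.02214076e23 * 1e9,       # kJ mol^-1 ps
  ke   = 138.935458                                  # Coulomb prefactor, kJ nm mol^-1 e^-2
)

#' Physical constants used by condensotherm
#'
#' Returns the CODATA-2018 constants in package units (nm, ps, amu, kJ/mol,
#' K): `kB` (kJ mol^-1 K^-1), `R` (J mol^-1 K^-1), `NA_` (mol^-1), `h`
#' (kJ mol^-1 ps) and the electrostatic prefactor `ke`
#' (kJ nm mol^-1 e^-2).
#'
#' @return Named list of constants.
#' @export
#' @examples
#' ct_constants()$kB * 300  # thermal energy at 300 K in kJ/mol
ct_constants <- function() .ct
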