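#' Molar gas constant in kJ/(mol K)
#'
#' @format Length-one numeric, 8.314462618e-3 kJ/(mol K).
#' @export
GAS_CONSTANT_KJ <- 8.314462618e-3

#' Elementary charge in coulomb
#' @format Length-one numeric.
#' @export
ELEMENTARY_CHARGE <- 1.602176634e-19

#' Thermal energy RT in kJ/mol
#'
#' @param temperature Temperature in kelvin.
#' @return RT in kJ/mol (about 2.66 kJ/mol at 320 K).
#' @export
rt_kjmol <- function(temperature = 320) {
  stopifnot(is.numeric(temperature), temperature > 0)
  GAS_CONSTANT_KJ * temperature
}
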