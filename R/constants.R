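# Physical constants. Energies kcal/mol, lengths A, volumes A^3 throughout.

# gas constant, kcal / (mol K)
.R_KCAL <- 1.987204259e-3
# gas constant, L kPa / (mol K) -- for gas-phase concentration <-> pressure
.R_LKPA <- 8.31446261815324
# Avogadro constant, 1/mol
.N_AVOGADRO <- 6.02214076e23
# reference pressure (1 atm) in kPa and reference concentration in mol/L
.P0_KPA <- 101.325
.C0_MOLL <- 1

# working temperature, K: all packaged energies refer to ambient conditions
.T_REF <- 298.15

#' Thermal energy RT
#'
#' @param temperature Temperature in K.
#' @return RT in kcal/mol (0.5925 at 298.15 K).
#' @examples
#' rt_kcal()
#' @export
rt_kcal <- function(temperature = 298.15) {
  stopifnot(is.numeric(temperature), temperature > 0)
  .R_KCAL * temperature
}
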