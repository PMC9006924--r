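# Free-energy bookkeeping: affinity ratios -> relative binding energies,
# solvation from solubility/vapor pressure, gas->cavity transfer, the
# cavitation/dispersion split, mixture additivity, and pre-association
# corrections for n-mer guests.

#' Relative binding free energy from an affinity ratio
#'
#' ddG = -RT ln(K_rel), with the standard error propagated first-order as
#' RT * K_rel_se / K_rel.
#'
#' @param K_rel Relative binding constant (> 0). Vectorized.
#' @param K_rel_se Optional standard error(s) of `K_rel`.
#' @param temperature Temperature in K.
#' @return If `K_rel_se` is `NULL`, a numeric vector (kcal/mol); otherwise a
#'   data frame with columns `dG` and `se`.
#' @examples
#' relative_binding_free_energy(110)        # cyclohexane vs benzene, -2.78
#' relative_binding_free_energy(110, 2)
#' @export
relative_binding_free_energy <- function(K_rel, K_rel_se = NULL,
                                         temperature = 298.15) {
  if (any(!is.finite(K_rel)) || any(K_rel <= 0)) {
    stop("relative_binding_free_energy: K_rel must be positive and finite")
  }
  rt <- rt_kcal(temperature)
  dg <- -rt * log(K_rel)
  if (is.null(K_rel_se)) return(dg)
  data.frame(dG = dg, se = rt * K_rel_se / K_rel)
}

#' Gas-phase standard-state correction
#'
#' Free-energy change of moving the gas reference state from 1 atm to
#' 1 mol/L: -RT ln(c0 RT / P0). At 298.15 K a 1 mol/L gas corresponds to
#' ~24.5 atm and the correction is -1.89 kcal/mol (commonly quoted as
#' -1.90).
#'
#' @param temperature Temperature in K.
#' @return Correction in kcal/mol.
#' @examples
#' standard_state_correction()
#' @export
standard_state_correction <- function(temperature = 298.15) {
  stopifnot(is.numeric(temperature), all(temperature > 0))
  ratio <- .C0_MOLL * .R_LKPA * temperature / .P0_KPA
  -rt_kcal(temperature) * log(ratio)
}

#' Solvation free energy from solubility and vapor pressure
#'
#' For a solute at saturation equilibrium with its own vapor, the solvation
#' free energy (1 M gas -> 1 M solution) is
#' dG_solv = -RT ln(S P0 / P_vap) + correction, where the correction is
#' [standard_state_correction()]. Equivalently
#' dG_solv = -RT ln(S c0 RT / P_vap), the two routes agreeing exactly.
#'
#' @param solubility Saturation solubility in mol/L (> 0).
#' @param vapor_pressure Vapor pressure in kPa (> 0).
#' @param temperature Temperature in K.
#' @param correct Apply the standard-state correction (default `TRUE`; set
#'   `FALSE` to obtain the 1 atm gas reference).
#' @return Solvation free energy in kcal/mol.
#' @examples
#' solvation_from_solubility(0.0228, 12.7)  # benzene in water, ~ -0.89
#' @export
solvation_from_solubility <- function(solubility, vapor_pressure,
                                      temperature = 298.15, correct = TRUE) {
  if (any(!is.finite(solubility)) || any(solubility <= 0) ||
      any(!is.finite(vapor_pressure)) || any(vapor_pressure <= 0)) {
    stop("solvation_from_solubility: solubility and vapor_pressure must be positive")
  }
  dg <- -rt_kcal(temperature) * log(solubility * .P0_KPA / vapor_pressure)
  if (correct) dg <- dg + standard_state_correction(temperature)
  dg
}

#' Transfer free energy from the gas phase
#'
#' Converts a relative transfer energy from aqueous solution into the
#' corresponding relative transfer energy from the gas phase by adding the
#' difference of the aqueous solvation energies of guest and reference:
#' ddG_gas = ddG_aq + (dG_solv_w(guest) - dG_solv_w(ref)).
#'
#' @param ddG_aq Relative transfer free energy from water, kcal/mol.
#' @param dG_solv_water_guest Aqueous solvation free energy of the guest.
#' @param dG_solv_water_ref Aqueous solvation free energy of the reference
#'   guest.
#' @return Relative transfer free energy from the gas phase, kcal/mol.
#' @examples
#' gas_to_cavity(-2.78, 1.02, -0.94)  # cyclohexane vs benzene, -0.82
#' @export
gas_to_cavity <- function(ddG_aq, dG_solv_water_guest, dG_solv_water_ref) {
  vals <- c(ddG_aq, dG_solv_water_guest, dG_solv_water_ref)
  if (any(!is.finite(vals))) stop("gas_to_cavity: all inputs must be finite")
  ddG_aq + (dG_solv_water_guest - dG_solv_water_ref)
}

#' Dispersive component of solvation
#'
#' The attractive remainder after removing the cavitation cost:
#' dG_disp = dG_solv - dG_cav.
#'
#' @param dG_solv Solvation free energy, kcal/mol.
#' @param dG_cav Cavitation free energy in the same solvent, kcal/mol.
#' @return Dispersion term in kcal/mol.
#' @examples
#' dispersive_term(2.54, 2.15)  # He in benzene, 0.39
#' @export
dispersive_term <- function(dG_solv, dG_cav) {
  dG_solv - dG_cav
}

#' Mixture dispersion term by molar-fraction additivity
#'
#' Dispersive interactions with a solvent mixture are taken as the
#' molar-fraction-weighted sum of the pure-solvent dispersion terms.
#'
#' @param terms Numeric vector of per-solvent dispersion terms, kcal/mol.
#' @param fractions Molar fractions, same length, summing to 1 (within
#'   1e-9).
#' @return Mixture dispersion term in kcal/mol.
#' @examples
#' mixture_dispersive(c(1.74, 0.39), c(0.68, 0.32))  # He, 68:32 mix, ~1.31
#' @export
mixture_dispersive <- function(terms, fractions) {
  stopifnot(length(terms) == length(fractions))
  if (any(fractions < 0 | fractions > 1)) {
    stop("mixture_dispersive: fractions must lie in [0, 1]")
  }
  if (abs(sum(fractions) - 1) > 1e-9) {
    stop(sprintf("mixture_dispersive: fractions sum to %.12f, not 1",
                 sum(fractions)))
  }
  sum(terms * fractions)
}

#' Pre-association correction for n-mer guests
#'
#' When a host encapsulates an n-mer (e.g. a methane dimer), the n-mer is
#' treated as a standalone guest and its transfer energy is corrected by the
#' free energy of the endergonic pre-association in solution:
#' dG_corrected = dG_transfer + dG_assoc.
#'
#' @param dG_transfer Transfer free energy of the n-mer guest, kcal/mol.
#' @param dG_assoc Free energy of forming the n-mer from monomers, kcal/mol
#'   (e.g. +1.76 for the methane dimer, +5.57 for the cyclic trimer).
#' @return Corrected transfer free energy in kcal/mol.
#' @examples
#' preassociation_correction(-5, 1.76)
#' @export
preassociation_correction <- function(dG_transfer, dG_assoc) {
  vals <- c(dG_transfer, dG_assoc)
  if (any(!is.finite(vals))) {
    stop("preassociation_correction: inputs must be finite")
  }
  dG_transfer + dG_assoc
}

#' Solvation energy decomposition for packaged guests
#'
#' Builds the cavitation/dispersion breakdown dG_solv = dG_cav + dG_disp
#' for guests in a named solvent, from the packaged (or user-supplied) guest
#' table columns `solv_<solvent>` and `cav_<solvent>`.
#'
#' @param guests Guest data frame (see [cb_guests()]).
#' @param solvent Solvent name matching the column suffix (e.g. `"benzene"`,
#'   `"pfh"`), or a [solvent_model()].
#' @return Data frame with columns `id`, `solvent`, `dG_solv`, `dG_cav`,
#'   `dG_disp` (dG_disp = dG_solv - dG_cav by construction).
#' @examples
#' head(energy_breakdown(cb_guests(), "benzene"))
#' @export
energy_breakdown <- function(guests, solvent) {
  if (inherits(solvent, "solvent_model")) solvent <- solvent$name
  sc <- paste0("solv_", solvent)
  cc <- paste0("cav_", solvent)
  for (col in c(sc, cc)) {
    if (!col %in% names(guests)) {
      stop("energy_breakdown: guest table lacks column '", col, "'")
    }
  }
  data.frame(id = guests$id, solvent = solvent,
             dG_solv = guests[[sc]], dG_cav = guests[[cc]],
             dG_disp = dispersive_term(guests[[sc]], guests[[cc]]),
             stringsAsFactors = FALSE)
}
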