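# Hard-sphere cavitation: effective diameters, packing fractions, and the
# cavitation free energy of opening a solute-sized cavity in a hard-sphere
# solvent (BMCSL equation of state, Matyushov-Ladanyi form).

#' Effective hard-sphere diameter from an isodensity volume
#'
#' Converts a computed molecular volume (isodensity surface) to an effective
#' hard-sphere diameter, sigma' = c * (6V/pi)^(1/3). The empirical
#' coefficient c = 0.922 absorbs the systematic offset between
#' isodensity-surface diameters and tabulated hard-sphere diameters.
#'
#' @param volume Molecular volume in cubic Angstrom (> 0). Vectorized.
#' @param c Calibration coefficient, dimensionless, in (0.8, 1].
#' @return Effective diameter in Angstrom.
#' @examples
#' effective_diameter(33.7)  # methane, ~3.70 A
#' @seealso [guest_volume()] for the inverse.
#' @export
effective_diameter <- function(volume, c = 0.922) {
  if (any(!is.finite(volume)) || any(volume <= 0)) {
    stop("effective_diameter: volume must be positive and finite")
  }
  stopifnot(c > 0.8, c <= 1)
  c * (6 * volume / pi)^(1 / 3)
}

#' Volume implied by an effective hard-sphere diameter
#'
#' Inverse of [effective_diameter()]: V = (pi/6) * (sigma/c)^3.
#'
#' @inheritParams effective_diameter
#' @param sigma Effective diameter in Angstrom.
#' @return Volume in cubic Angstrom.
#' @export
guest_volume <- function(sigma, c = 0.922) {
  if (any(!is.finite(sigma)) || any(sigma <= 0)) {
    stop("guest_volume: sigma must be positive and finite")
  }
  (pi / 6) * (sigma / c)^3
}

#' Solvent packing fraction from bulk properties
#'
#' eta = (pi/6) * N_A * (rho/M) * sigma^3 * 1e-24, the fraction of the
#' liquid volume occupied by solvent hard spheres.
#'
#' @param sigma Solvent hard-sphere diameter in Angstrom.
#' @param density Bulk density in g/cm^3.
#' @param molar_mass Molar mass in g/mol.
#' @return Dimensionless packing fraction in (0, 0.74).
#' @examples
#' packing_fraction(5.16, 0.874, 78.11)  # benzene, ~0.485
#' @export
packing_fraction <- function(sigma, density, molar_mass) {
  if (any(c(sigma, density, molar_mass) <= 0) ||
      any(!is.finite(c(sigma, density, molar_mass)))) {
    stop("packing_fraction: all inputs must be positive and finite")
  }
  eta <- (pi / 6) * .N_AVOGADRO * (density / molar_mass) * sigma^3 * 1e-24
  if (any(eta >= 0.74)) {
    stop(sprintf(paste0("packing_fraction: eta = %.4f >= 0.74 (beyond close",
                        " packing) for sigma = %.3f, rho = %.3f, M = %.2f"),
                 max(eta), sigma[which.max(eta)][1], density[1], molar_mass[1]))
  }
  eta
}

# Carnahan-Starling hard-sphere compressibility factor
.z_cs <- function(eta) (1 + eta + eta^2 - eta^3) / (1 - eta)^3

#' Hard-sphere cavitation free energy
#'
#' Free-energy cost of opening a spherical cavity that accommodates a
#' hard-sphere solute of diameter ratio `d` (solute/solvent) in a solvent of
#' packing fraction `eta`, from the BMCSL equation of state in the
#' Matyushov-Ladanyi form:
#'
#' beta dG = -ln(1-eta) + 3eta/(1-eta) d
#'           + \[3eta/(1-eta) + (9/2)(eta/(1-eta))^2\] d^2 + eta Z(eta) d^3
#'
#' with Z the Carnahan-Starling compressibility factor. Strictly increasing
#' in both `d` and `eta`; reduces to -RT ln(1-eta) for a point solute and
#' vanishes as eta -> 0.
#'
#' @param d Solute/solvent diameter ratio (>= 0). Vectorized.
#' @param eta Solvent packing fraction in (0, 0.74).
#' @param temperature Temperature in K.
#' @return Cavitation free energy in kcal/mol.
#' @examples
#' bz <- cb_solvents()$benzene
#' cavitation_energy(3.70 / bz$sigma, bz$eta)  # methane in benzene, ~4.9
#' @export
cavitation_energy <- function(d, eta, temperature = 298.15) {
  if (any(!is.finite(d)) || any(d < 0)) {
    stop("cavitation_energy: d must be finite and >= 0")
  }
  if (any(!is.finite(eta)) || any(eta <= 0) || any(eta >= 0.74)) {
    stop("cavitation_energy: eta must lie in (0, 0.74)")
  }
  r <- eta / (1 - eta)
  beta_dg <- -log(1 - eta) + 3 * r * d + (3 * r + 4.5 * r^2) * d^2 +
    eta * .z_cs(eta) * d^3
  rt_kcal(temperature) * beta_dg
}

#' Cavitation free energy of a guest in a mimic solvent
#'
#' Convenience wrapper: takes guest effective diameters and a
#' [solvent_model()], forms the diameter ratio and evaluates
#' [cavitation_energy()] at the solvent's packing fraction and temperature.
#'
#' @param sigma_prime Guest effective hard-sphere diameter(s), Angstrom.
#' @param solvent A [solvent_model()].
#' @return Cavitation free energies in kcal/mol.
#' @export
solvent_cavitation <- function(sigma_prime, solvent) {
  stopifnot(inherits(solvent, "solvent_model"))
  cavitation_energy(sigma_prime / solvent$sigma, solvent$eta,
                    solvent$temperature)
}

#' Calibrate a mimic solvent against anchor cavitation energies
#'
#' Least-squares fit of the solvent hard-sphere parameters to a set of
#' anchor guests with known cavitation energies. Two modes:
#' `fit = "sigma"` fits the diameter alone with the packing fraction tied to
#' the bulk density via [packing_fraction()]; `fit = "sigma_eta"` fits both,
#' decoupling eta from the density (used for perfluorohexane, whose
#' effective packing differs from the density-implied value).
#'
#' @param name Solvent name for the returned model.
#' @param anchors Named numeric vector: guest id -> cavitation energy
#'   (kcal/mol). At least 2 anchors.
#' @param guests Guest table containing columns `id` and `sigma_prime`
#'   covering every anchor id.
#' @param density,molar_mass Bulk solvent properties (g/cm^3, g/mol).
#' @param fit `"sigma"` or `"sigma_eta"`.
#' @param max_residual Refuse the fit if any anchor residual exceeds this
#'   (kcal/mol).
#' @param temperature Temperature in K.
#' @return A [solvent_model()] with attribute `"residuals"` (named, per
#'   anchor, kcal/mol).
#' @examples
#' g <- cb_guests()
#' calibrate_solvent("benzene", c(`1` = 4.89, `19` = 12.11), g,
#'                   density = 0.874, molar_mass = 78.11)
#' @export
calibrate_solvent <- function(name, anchors, guests, density, molar_mass,
                              fit = c("sigma", "sigma_eta"),
                              max_residual = 0.3, temperature = 298.15) {
  fit <- match.arg(fit)
  if (length(anchors) < 2) stop("calibrate_solvent: need at least 2 anchors")
  if (is.null(names(anchors)) || any(!nzchar(names(anchors)))) {
    stop("calibrate_solvent: anchors must be named by guest id")
  }
  idx <- match(names(anchors), as.character(guests$id))
  if (anyNA(idx)) {
    stop("calibrate_solvent: unknown anchor guest(s): ",
         paste(names(anchors)[is.na(idx)], collapse = ", "))
  }
  sp <- guests$sigma_prime[idx]
  if (anyNA(sp)) stop("calibrate_solvent: anchor guests lack sigma_prime")
  target <- as.numeric(anchors)

  sse_sigma <- function(sigma) {
    eta <- (pi / 6) * .N_AVOGADRO * (density / molar_mass) * sigma^3 * 1e-24
    if (eta <= 0 || eta >= 0.74) return(1e10)
    sum((cavitation_energy(sp / sigma, eta, temperature) - target)^2)
  }
  sse_both <- function(par) {
    if (par[1] <= 0 || par[2] <= 0 || par[2] >= 0.74) return(1e10)
    sum((cavitation_energy(sp / par[1], par[2], temperature) - target)^2)
  }

  if (fit == "sigma") {
    opt <- stats::optimize(sse_sigma, interval = c(2, 12), tol = 1e-10)
    sigma <- opt$minimum
    model <- solvent_model(name, sigma, density, molar_mass, temperature)
  } else {
    start <- c(5, 0.4)
    opt <- stats::optim(start, sse_both, control = list(reltol = 1e-14,
                                                        maxit = 5000))
    opt <- stats::optim(opt$par, sse_both,
                        control = list(reltol = 1e-14, maxit = 5000))
    if (opt$convergence != 0) {
      stop("calibrate_solvent: optimizer failed to converge")
    }
    model <- solvent_model(name, opt$par[1], density, molar_mass,
                           temperature, eta = opt$par[2])
  }
  res <- solvent_cavitation(sp, model) - target
  names(res) <- names(anchors)
  if (max(abs(res)) > max_residual) {
    stop(sprintf(paste0("calibrate_solvent: max anchor residual %.3f kcal/mol",
                        " exceeds %.3f; refusing fit"),
         max(abs(res)), max_residual))
  }
  attr(model, "residuals") <- res
  model
}
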