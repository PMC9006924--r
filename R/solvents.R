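#' Hard-sphere solvent model
#'
#' A mimic solvent is described by a hard-sphere diameter `sigma`, its bulk
#' density and molar mass, and the packing fraction `eta` (the volume
#' fraction occupied by solvent spheres). By default `eta` is derived from
#' `sigma`, `density` and `molar_mass` via [packing_fraction()]; calibrated
#' solvents may override it with a fitted value (see [calibrate_solvent()]),
#' in which case `eta_derived` is `FALSE`.
#'
#' @param name Solvent identifier, e.g. `"benzene"`. Also used as the column
#'   suffix (`solv_<name>`, `cav_<name>`) when looking up guest data.
#' @param sigma Hard-sphere diameter in Angstrom.
#' @param density Bulk density in g/cm^3.
#' @param molar_mass Molar mass in g/mol.
#' @param temperature Temperature in K.
#' @param eta Optional packing-fraction override; if `NULL`, derived from
#'   the other fields.
#' @return An object of class `solvent_model`.
#' @examples
#' solvent_model("benzene", sigma = 5.16, density = 0.874, molar_mass = 78.11)
#' @seealso [solvent_mixture()], [cb_solvents()]
#' @export
solvent_model <- function(name, sigma, density, molar_mass,
                          temperature = 298.15, eta = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  for (v in c(sigma = sigma, density = density, molar_mass = molar_mass,
              temperature = temperature)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("solvent_model: sigma, density, molar_mass and temperature must be positive scalars")
    }
  }
  eta_derived <- is.null(eta)
  if (eta_derived) {
    eta <- packing_fraction(sigma, density, molar_mass)
  }
  if (!is.finite(eta) || eta <= 0 || eta >= 0.74) {
    stop(sprintf("solvent_model: packing fraction %.4f outside (0, 0.74)", eta))
  }
  structure(
    list(name = name, sigma = sigma, density = density,
         molar_mass = molar_mass, temperature = temperature,
         eta = eta, eta_derived = eta_derived),
    class = "solvent_model"
  )
}

#' @export
print.solvent_model <- function(x, ...) {
  cat(sprintf("Hard-sphere solvent '%s'\n", x$name))
  cat(sprintf("  sigma = %.4f A, rho = %.3f g/cm^3, M = %.2f g/mol\n",
              x$sigma, x$density, x$molar_mass))
  cat(sprintf("  eta   = %.4f (%s), T = %.2f K\n", x$eta,
              if (x$eta_derived) "derived from density" else "calibrated override",
              x$temperature))
  invisible(x)
}

#' Binary (or n-ary) solvent mixture
#'
#' Combines solvent models with molar fractions. Only the dispersive term of
#' solvation is treated as additive across components (see
#' [mixture_dispersive()]); no mixture cavitation model is defined.
#'
#' @param solvents List of [solvent_model()] objects.
#' @param fractions Molar fractions, same length, in \[0, 1\] summing to 1.
#' @return An object of class `solvent_mixture`.
#' @examples
#' sv <- cb_solvents()
#' solvent_mixture(list(sv$pfh, sv$benzene), c(0.68, 0.32))
#' @export
solvent_mixture <- function(solvents, fractions) {
  if (inherits(solvents, "solvent_model")) solvents <- list(solvents)
  stopifnot(is.list(solvents), length(solvents) == length(fractions))
  ok <- vapply(solvents, inherits, logical(1), "solvent_model")
  if (!all(ok)) stop("solvent_mixture: every component must be a solvent_model")
  if (any(fractions < 0 | fractions > 1)) {
    stop("solvent_mixture: fractions must lie in [0, 1]")
  }
  if (abs(sum(fractions) - 1) > 1e-9) {
    stop(sprintf("solvent_mixture: fractions sum to %.12f, not 1", sum(fractions)))
  }
  structure(
    list(solvents = solvents, fractions = as.numeric(fractions)),
    class = "solvent_mixture"
  )
}

#' @export
print.solvent_mixture <- function(x, ...) {
  comp <- paste(sprintf("%.0f%% %s", 100 * x$fractions,
                        vapply(x$solvents, `[[`, character(1), "name")),
                collapse = " / ")
  cat("Solvent mixture:", comp, "\n")
  invisible(x)
}

#' Packaged mimic-solvent registry
#'
#' Benzene and perfluorohexane, the two mimic solvents used to characterize
#' cucurbituril cavities. The hard-sphere diameters are calibrated
#' parameters, fitted once against the packaged cavitation energies of the
#' 21 hydrocarbon guests (see [calibrate_solvent()]): benzene keeps its
#' packing fraction tied to the bulk density, perfluorohexane carries a
#' fitted packing-fraction override.
#'
#' @return Named list with elements `benzene` and `pfh`.
#' @examples
#' cb_solvents()$benzene
#' @export
cb_solvents <- function() {
  list(
    benzene = solvent_model("benzene", sigma = 5.16077,
                            density = 0.874, molar_mass = 78.11),
    pfh = solvent_model("pfh", sigma = 5.16273,
                        density = 1.669, molar_mass = 338.04,
                        eta = 0.28396)
  )
}
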