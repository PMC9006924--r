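# Seeded generators producing synthetic inputs with the statistical
# structure the estimators assume, so every regression is testable without
# measured data.

#' Simulate a competitive titration series
#'
#' Forward-simulates the fast-exchange observable: for each design point the
#' bound-complex ratio is r = K (x_H S0_H) / (x_H' S0_H'), the noiseless
#' shift is the population-weighted endpoint average
#' (r delta_H + delta_H') / (1 + r), and Gaussian noise of sd `noise_sd` is
#' added to the shifts. Points whose noisy shift falls outside the open
#' endpoint interval are clamped just inside it (relevant only at extreme
#' noise).
#'
#' The default design places 8 points with bound fractions of guest H evenly
#' spaced over \[0.2, 0.8\], i.e. observed shifts spanning the central 60%
#' of the endpoint separation, and solves for the corresponding molar
#' fractions given `true_K_rel`; pass `design` (a vector of x_H fractions)
#' to override. Endpoint shifts and solubilities default to a
#' cyclohexane/cycloheptene-like competition.
#'
#' @param true_K_rel Generating relative binding constant (> 0).
#' @param delta_H,delta_Hprime Endpoint shifts, ppm.
#' @param S0_H,S0_Hprime Pure-compound solubilities, mol/L.
#' @param n_points Number of points for the automatic design.
#' @param design Optional vector of x_H molar fractions in (0, 1).
#' @param noise_sd Gaussian shift noise, ppm (>= 0).
#' @param seed Integer seed; same seed, same series.
#' @param guest_H,guest_Hprime Labels for the simulated guests.
#' @return A [titration_series()].
#' @examples
#' ts <- simulate_titration(true_K_rel = 448, noise_sd = 0, seed = 1)
#' fit_competition(ts)$K_rel
#' @export
simulate_titration <- function(true_K_rel, delta_H = -57.94,
                               delta_Hprime = -58.52, S0_H = 1.1e-4,
                               S0_Hprime = 2.5e-4, n_points = 8,
                               design = NULL, noise_sd = 0.005, seed = NULL,
                               guest_H = "H", guest_Hprime = "Hprime") {
  stopifnot(is.numeric(true_K_rel), true_K_rel > 0, noise_sd >= 0)
  if (delta_H == delta_Hprime) {
    stop("simulate_titration: endpoint shifts must differ")
  }
  if (!is.null(seed)) set.seed(seed)
  if (is.null(design)) {
    # target bound fractions of H evenly spaced; invert r = K x S0H/((1-x) S0H')
    p <- seq(0.2, 0.8, length.out = n_points)
    r <- p / (1 - p)
    ratio_x <- r / (true_K_rel * S0_H / S0_Hprime)  # x_H / (1 - x_H)
    design <- ratio_x / (1 + ratio_x)
  }
  if (any(design <= 0 | design >= 1)) {
    stop("simulate_titration: design fractions must lie strictly in (0, 1)")
  }
  r <- true_K_rel * mixture_solubility(design, S0_H) /
    mixture_solubility(1 - design, S0_Hprime)
  delta <- (r * delta_H + delta_Hprime) / (1 + r)
  if (noise_sd > 0) delta <- delta + stats::rnorm(length(delta), 0, noise_sd)
  # keep shifts inside the open endpoint interval
  lo <- min(delta_H, delta_Hprime); hi <- max(delta_H, delta_Hprime)
  eps <- 1e-9 * (hi - lo)
  delta <- pmin(pmax(delta, lo + eps), hi - eps)
  titration_series(guest_H, guest_Hprime, delta_H, delta_Hprime,
                   S0_H, S0_Hprime, x_H = design, delta_obs = delta)
}

#' Simulate a host transfer-energy dataset
#'
#' Draws transfer free energies from the linear pre-formed cavity model:
#' y = true_slope * (dG_solv - dG_cav) + true_intercept + Gaussian noise,
#' with optional planted outliers shifted by `outlier_shift`.
#'
#' @param guests Guest data frame providing the mimic-solvent terms.
#' @param mimic A [solvent_model()] or [solvent_mixture()].
#' @param guest_ids Guest ids forming the panel (default: the nine rigid
#'   hydrocarbons of the packaged competitive-titration panel).
#' @param true_slope,true_intercept Generating coefficients (kcal/mol for
#'   the intercept).
#' @param residual_sd Gaussian energy noise, kcal/mol (>= 0).
#' @param outlier_ids Optional ids shifted by `outlier_shift` after noise.
#' @param outlier_shift Shift applied to outliers, kcal/mol.
#' @param seed Integer seed; same seed, same dataset.
#' @param host Name for the simulated host.
#' @return A [host_data()] with absolute energies.
#' @examples
#' hd <- simulate_host(true_slope = 1, true_intercept = -0.7,
#'                     residual_sd = 0, seed = 1)
#' characterize_cavity(hd, mimic = cb_solvents()$benzene)$fit$slope
#' @export
simulate_host <- function(guests = cb_guests(), mimic = cb_solvents()$benzene,
                          guest_ids = c("12", "13", "14", "15", "16", "17",
                                        "18", "19", "21"),
                          true_slope = 1, true_intercept = 0,
                          residual_sd = 0, outlier_ids = NULL,
                          outlier_shift = 0, seed = NULL,
                          host = "simulated") {
  stopifnot(residual_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  x <- dispersion_terms(guests, mimic, ids = guest_ids)
  if (anyNA(x)) {
    stop("simulate_host: missing mimic data for guest(s): ",
         paste(guest_ids[is.na(x)], collapse = ", "))
  }
  y <- true_slope * unname(x) + true_intercept
  if (residual_sd > 0) y <- y + stats::rnorm(length(y), 0, residual_sd)
  if (!is.null(outlier_ids)) {
    j <- match(as.character(outlier_ids), guest_ids)
    if (anyNA(j)) stop("simulate_host: outlier ids must belong to the panel")
    y[j] <- y[j] + outlier_shift
  }
  host_data(host, stats::setNames(y, guest_ids))
}
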