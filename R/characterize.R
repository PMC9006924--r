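# Cavity characterization: the model's central claim as computation. Host
# gas->cavity transfer energies are regressed against the energy released
# upon inserting each guest into a pre-formed cavity in a mimic solvent
# (dG_solv - dG_cav). A unity slope means the mimic matches the cavity's
# polarizability; the intercept absorbs host-side constants (cavity
# desolvation), which is why the model predicts selectivity, not absolute
# affinity.

#' Pre-formed cavity energy terms for a set of guests
#'
#' Builds the regressor of the model: per guest, the dispersion energy
#' released on insertion into a pre-formed cavity, dG_solv - dG_cav, in a
#' mimic solvent or mixture. For a pure solvent the packaged columns
#' `solv_<name>` / `cav_<name>` are used; where a cavitation cell is missing
#' but `sigma_prime` is available, it is computed from the solvent model via
#' [solvent_cavitation()]. Mixture terms are molar-fraction-weighted sums of
#' the pure-solvent dispersion terms ([mixture_dispersive()]).
#'
#' @param guests Guest data frame (see [cb_guests()]).
#' @param mimic A [solvent_model()] or [solvent_mixture()].
#' @param ids Optional guest ids to restrict to (default: all rows).
#' @return Named numeric vector of dispersion terms (kcal/mol) keyed by
#'   guest id; `NA` where data are missing.
#' @examples
#' dispersion_terms(cb_guests(), cb_solvents()$benzene, ids = c("1", "18"))
#' @export
dispersion_terms <- function(guests, mimic, ids = NULL) {
  if (!is.null(ids)) {
    idx <- match(as.character(ids), as.character(guests$id))
    if (anyNA(idx)) {
      stop("dispersion_terms: unknown guest id(s): ",
           paste(ids[is.na(idx)], collapse = ", "))
    }
    guests <- guests[idx, , drop = FALSE]
  }
  one_solvent <- function(sv) {
    sc <- paste0("solv_", sv$name)
    cc <- paste0("cav_", sv$name)
    if (!sc %in% names(guests)) {
      stop("dispersion_terms: guest table lacks column '", sc, "'")
    }
    cav <- if (cc %in% names(guests)) guests[[cc]] else rep(NA_real_,
                                                            nrow(guests))
    fill <- is.na(cav) & !is.na(guests$sigma_prime)
    if (any(fill)) {
      cav[fill] <- solvent_cavitation(guests$sigma_prime[fill], sv)
    }
    dispersive_term(guests[[sc]], cav)
  }
  if (inherits(mimic, "solvent_model")) {
    x <- one_solvent(mimic)
  } else if (inherits(mimic, "solvent_mixture")) {
    per <- vapply(mimic$solvents, one_solvent, numeric(nrow(guests)))
    per <- matrix(per, nrow = nrow(guests))
    x <- as.numeric(per %*% mimic$fractions)
  } else {
    stop("dispersion_terms: mimic must be a solvent_model or solvent_mixture")
  }
  stats::setNames(x, as.character(guests$id))
}

#' Characterize a host cavity against a mimic solvent
#'
#' Fits the pre-formed cavity model for one host: ordinary least squares of
#' the host's gas->cavity transfer free energies on the mimic-solvent
#' dispersion terms dG_solv - dG_cav (see [dispersion_terms()]). For hosts
#' whose energies are relative to a reference guest, both axes are shifted
#' to that reference (slope and R^2 are unaffected; the intercept is then
#' reference-relative).
#'
#' @param host A [host_data()] (e.g. from [cb_host()]).
#' @param guests Guest data frame covering every included guest (default
#'   [cb_guests()]).
#' @param mimic A [solvent_model()] or [solvent_mixture()].
#' @param exclusions Guest ids to exclude. Defaults to the host's curated
#'   exclusion list; pass `character()` to keep every guest.
#' @param slope If non-`NULL`, fix the slope (e.g. `1` for a unity-slope
#'   outlier screen) and fit the intercept only.
#' @return Object of class `cavity_fit` with elements `host`, `mimic`,
#'   `fit` (an [ols()] result), `data` (id, x, y), `excluded`,
#'   `reference_guest`; methods: `print`, `summary`, `coef`, `residuals`,
#'   `predict`, `plot`.
#' @examples
#' cf <- characterize_cavity(cb_host("CB6"), mimic = cb_solvents()$pfh)
#' coef(cf)
#' @export
characterize_cavity <- function(host, guests = cb_guests(), mimic,
                                exclusions = NULL, slope = NULL) {
  stopifnot(inherits(host, "host_data"))
  if (is.null(exclusions)) exclusions <- host$exclusions$id
  ids <- setdiff(names(host$transfer), exclusions)
  if (length(ids) < 2) stop("characterize_cavity: fewer than 2 included guests")
  x <- dispersion_terms(guests, mimic, ids = ids)
  if (anyNA(x)) {
    stop("characterize_cavity: missing mimic-solvent data for guest(s): ",
         paste(ids[is.na(x)], collapse = ", "))
  }
  y <- host$transfer[ids]
  ref <- host$reference_guest
  if (!identical(ref, "absolute")) {
    xref <- dispersion_terms(guests, mimic, ids = ref)
    if (is.na(xref)) {
      stop("characterize_cavity: missing mimic data for reference guest ", ref)
    }
    x <- x - as.numeric(xref)
  }
  fit <- ols(unname(x), unname(y), ids = ids, slope = slope)
  structure(
    list(host = host, mimic = mimic, fit = fit,
         data = data.frame(id = ids, x = unname(x), y = unname(y),
                           stringsAsFactors = FALSE),
         excluded = exclusions, reference_guest = ref),
    class = "cavity_fit"
  )
}

#' @export
print.cavity_fit <- function(x, ...) {
  mim <- if (inherits(x$mimic, "solvent_model")) x$mimic$name else {
    paste(sprintf("%.0f%% %s", 100 * x$mimic$fractions,
                  vapply(x$mimic$solvents, `[[`, character(1), "name")),
          collapse = "/")
  }
  cat(sprintf("Pre-formed cavity characterization: %s mimicked by %s\n",
              x$host$host, mim))
  cat(sprintf("  n = %d guest(s)%s%s\n", x$fit$n,
              if (length(x$excluded))
                paste0(", excluded: ", paste(x$excluded, collapse = ", "))
              else "",
              if (identical(x$reference_guest, "absolute")) ""
              else paste0(" (energies relative to guest ",
                          x$reference_guest, ")")))
  cat(sprintf("  slope = %.3f (se %s): mimic polarizability match\n",
              x$fit$slope,
              ifelse(is.na(x$fit$slope_se), "NA",
                     sprintf("%.3f", x$fit$slope_se))))
  cat(sprintf("  intercept = %.3f (se %s): host-side constant (cavity desolvation)\n",
              x$fit$intercept,
              ifelse(is.na(x$fit$intercept_se), "NA",
                     sprintf("%.3f", x$fit$intercept_se))))
  cat(sprintf("  R^2 = %.3f\n", x$fit$r_squared))
  invisible(x)
}

#' @export
summary.cavity_fit <- function(object, ...) {
  print(object)
  cat("  residuals (kcal/mol):\n")
  r <- object$fit$residuals
  for (i in seq_along(r)) cat(sprintf("    %-4s %7.3f\n", names(r)[i], r[i]))
  invisible(object)
}

#' @export
coef.cavity_fit <- function(object, ...) coef(object$fit)

#' @export
residuals.cavity_fit <- function(object, ...) object$fit$residuals

#' Predict transfer free energies for new guests
#'
#' Applies a fitted cavity characterization to new guests:
#' yhat = slope * x + intercept, with x the mimic-solvent dispersion term.
#' The prediction standard error combines the coefficient covariance with
#' the residual variance (first order). Guests larger than the largest guest
#' used in the fit trigger a warning: the model only holds while the guest
#' fits the cavity, so extrapolation beyond the fitted size range is
#' unreliable.
#'
#' @param object A `cavity_fit`.
#' @param guests Guest data frame containing the new guests.
#' @param ids Guest ids to predict (default: all rows of `guests`).
#' @param ... Unused.
#' @return Data frame with columns `id`, `x`, `predicted`, `se` (kcal/mol;
#'   relative to the fit's reference guest if the host dataset is relative).
#' @examples
#' cf <- characterize_cavity(cb_host("CB6"), mimic = cb_solvents()$pfh)
#' predict(cf, ids = "13")
#' @export
predict.cavity_fit <- function(object, guests = cb_guests(), ids = NULL, ...) {
  if (is.null(ids)) ids <- as.character(guests$id)
  x <- dispersion_terms(guests, object$mimic, ids = ids)
  if (anyNA(x)) {
    stop("predict.cavity_fit: missing mimic-solvent data for guest(s): ",
         paste(ids[is.na(x)], collapse = ", "))
  }
  if (!identical(object$reference_guest, "absolute")) {
    xref <- dispersion_terms(guests, object$mimic,
                             ids = object$reference_guest)
    x <- x - as.numeric(xref)
  }
  # size guard: the model holds only while the guest fits the cavity
  idx <- match(ids, as.character(guests$id))
  sp_new <- guests$sigma_prime[idx]
  fit_idx <- match(object$data$id, as.character(guests$id))
  sp_max <- suppressWarnings(max(guests$sigma_prime[fit_idx], na.rm = TRUE))
  if (is.finite(sp_max) && any(!is.na(sp_new) & sp_new > sp_max)) {
    warning("predict.cavity_fit: guest(s) ",
            paste(ids[!is.na(sp_new) & sp_new > sp_max], collapse = ", "),
            " exceed the largest fitted guest (sigma' ",
            sprintf("%.2f", sp_max),
            " A); the pre-formed cavity model may not hold")
  }
  if (object$fit$fixed_slope) {
    yhat <- object$fit$slope * unname(x) + object$fit$intercept
    se <- sqrt(object$fit$intercept_se^2 + object$fit$sigma^2)
    se <- rep(se, length(x))
  } else {
    pr <- stats::predict(object$fit$lm,
                         newdata = data.frame(x = unname(x)),
                         se.fit = TRUE)
    yhat <- unname(pr$fit)
    se <- sqrt(unname(pr$se.fit)^2 + object$fit$sigma^2)
  }
  data.frame(id = ids, x = unname(x), predicted = yhat, se = se,
             stringsAsFactors = FALSE)
}

#' @export
plot.cavity_fit <- function(x, ...) {
  dat <- x$data
  graphics::plot(dat$x, dat$y,
                 xlab = "dG_solv - dG_cav in mimic (kcal/mol)",
                 ylab = "gas -> cavity transfer (kcal/mol)",
                 main = sprintf("%s: slope %.2f, R^2 %.2f", x$host$host,
                                x$fit$slope, x$fit$r_squared), ...)
  graphics::abline(x$fit$intercept, x$fit$slope)
  graphics::text(dat$x, dat$y, labels = dat$id, pos = 3, cex = 0.7)
  invisible(x)
}

#' Find the mixture fraction that gives a target slope
#'
#' Scans binary mixtures of two mimic solvents for the molar fraction of
#' solvent A at which the cavity characterization slope equals
#' `target_slope` (default 1: the mixture whose polarizability matches the
#' cavity). The slope is monotone in the fraction for well-behaved data;
#' the root is found by bisection to `tol` in the fraction.
#'
#' @param host A [host_data()].
#' @param guests Guest data frame.
#' @param solventA,solventB [solvent_model()] objects.
#' @param target_slope Target slope (default 1).
#' @param exclusions Guest ids to exclude (default: host's curated list).
#' @param tol Bisection tolerance on the fraction.
#' @return List with `fraction` (molar fraction of `solventA`) and
#'   `characterization` (the `cavity_fit` at the optimum).
#' @examples
#' sv <- cb_solvents()
#' opt <- optimize_mixture_fraction(cb_host("CB5"), cb_guests(),
#'                                  sv$pfh, sv$benzene)
#' round(opt$fraction, 2)
#' @export
optimize_mixture_fraction <- function(host, guests = cb_guests(), solventA,
                                      solventB, target_slope = 1,
                                      exclusions = NULL, tol = 1e-4) {
  slope_at <- function(f) {
    mim <- if (f >= 1) solventA else if (f <= 0) solventB else
      solvent_mixture(list(solventA, solventB), c(f, 1 - f))
    characterize_cavity(host, guests, mim, exclusions = exclusions)
  }
  lo <- slope_at(0)$fit$slope
  hi <- slope_at(1)$fit$slope
  if ((lo - target_slope) * (hi - target_slope) > 0) {
    stop(sprintf(paste0("optimize_mixture_fraction: no root in [0, 1]; slope",
                        " is %.3f in pure %s and %.3f in pure %s"),
                 lo, solventB$name, hi, solventA$name))
  }
  root <- stats::uniroot(function(f) slope_at(f)$fit$slope - target_slope,
                         interval = c(0, 1), tol = tol)
  list(fraction = root$root, characterization = slope_at(root$root))
}

#' Correlate host transfer energies with a guest descriptor
#'
#' OLS of the host's gas->cavity transfer free energies on a scalar guest
#' descriptor (static polarizability, volume, or solvent-accessible surface
#' area). For relative host datasets both axes are shifted to the reference
#' guest.
#'
#' @param host A [host_data()].
#' @param guests Guest data frame with the descriptor column (`alpha`,
#'   `volume`, or `sasa`).
#' @param descriptor One of `"alpha"`, `"volume"`, `"sasa"`.
#' @param exclusions Guest ids to exclude (default: host's curated list).
#' @return An [ols()] fit.
#' @examples
#' correlate_descriptor(cb_host("CB8.P3"), descriptor = "alpha")$r_squared
#' @export
correlate_descriptor <- function(host, guests = cb_guests(),
                                 descriptor = c("alpha", "volume", "sasa"),
                                 exclusions = NULL) {
  descriptor <- match.arg(descriptor)
  if (!descriptor %in% names(guests)) {
    stop("correlate_descriptor: guest table lacks column '", descriptor, "'")
  }
  if (is.null(exclusions)) exclusions <- host$exclusions$id
  ids <- setdiff(names(host$transfer), exclusions)
  idx <- match(ids, as.character(guests$id))
  if (anyNA(idx)) {
    stop("correlate_descriptor: unknown guest id(s): ",
         paste(ids[is.na(idx)], collapse = ", "))
  }
  d <- guests[[descriptor]][idx]
  if (anyNA(d)) {
    stop("correlate_descriptor: missing ", descriptor, " for guest(s): ",
         paste(ids[is.na(d)], collapse = ", "))
  }
  y <- host$transfer[ids]
  if (!identical(host$reference_guest, "absolute")) {
    dref <- guests[[descriptor]][match(host$reference_guest,
                                       as.character(guests$id))]
    d <- d - dref
  }
  ols(d, unname(y), ids = ids)
}

#' Flag outlier guests in a cavity fit
#'
#' Default rule: a guest is flagged if its absolute studentized residual
#' exceeds `threshold`, or if it belongs to the curated exclusion list
#' (guests the model is known not to apply to: too large to fit the cavity,
#' or binding as an n-mer). Curated reasons are carried through verbatim.
#'
#' @param fit A `cavity_fit` or [ols()] result with at least 4 points.
#' @param threshold Studentized-residual cutoff (default 2.5).
#' @param curated Optional data frame with columns `id`, `reason`; for a
#'   `cavity_fit` defaults to the host's curated list (restricted to guests
#'   actually present in the fit).
#' @return Data frame with columns `id` and `reason` (empty if no outliers).
#' @examples
#' cf <- characterize_cavity(cb_host("CB8.P3"), mimic = cb_solvents()$benzene)
#' flag_outliers(cf)
#' @export
flag_outliers <- function(fit, threshold = 2.5, curated = NULL) {
  if (inherits(fit, "cavity_fit")) {
    if (is.null(curated)) {
      curated <- fit$host$exclusions
      curated <- curated[curated$id %in% fit$data$id, , drop = FALSE]
    }
    fit <- fit$fit
  }
  stopifnot(inherits(fit, "ols_fit"))
  if (fit$n < 4) stop("flag_outliers: need at least 4 points")
  if (is.null(curated)) {
    curated <- data.frame(id = character(), reason = character(),
                          stringsAsFactors = FALSE)
  }
  st <- studentized_residuals(fit)
  stat_ids <- names(st)[!is.na(st) & abs(st) > threshold]
  stat_ids <- setdiff(stat_ids, curated$id)
  out <- rbind(
    curated[, c("id", "reason")],
    data.frame(id = stat_ids,
               reason = sprintf("studentized residual %.2f",
                                st[stat_ids]),
               stringsAsFactors = FALSE)
  )
  rownames(out) <- NULL
  out
}
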