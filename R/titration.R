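# Competitive fast-exchange 19F NMR titrations: two hydrocarbons H and H'
# compete for the same host cavity; the observed reporter shift is the
# population-weighted average of the two pure-complex endpoint shifts, and
# the ratio of bound populations against the ratio of free-solute
# concentrations (ideal-mixture solubilities) yields the relative binding
# constant as a regression slope.

#' Solubility of a solute in an ideal solute mixture
#'
#' S = x * S0: in an ideal mixture of excess solutes, each component's
#' aqueous solubility scales with its molar fraction in the mixture.
#'
#' @param x Molar fraction in \[0, 1\].
#' @param S0 Pure-compound solubility in mol/L (> 0).
#' @return Solubility in mol/L.
#' @examples
#' mixture_solubility(0.5, 0.002)
#' @export
mixture_solubility <- function(x, S0) {
  if (any(x < 0 | x > 1)) stop("mixture_solubility: x must lie in [0, 1]")
  if (any(!is.finite(S0)) || any(S0 <= 0)) {
    stop("mixture_solubility: S0 must be positive")
  }
  x * S0
}

#' Bound-complex ratio from an observed fast-exchange shift
#'
#' Under fast exchange the observed shift is the population average of the
#' endpoint shifts, so the ratio of the two bound complexes is
#' (delta - delta_Hprime) / (delta_H - delta).
#'
#' @param delta_obs Observed chemical shift(s), ppm; must lie strictly
#'   between the endpoints.
#' @param delta_H Shift of the pure complex with guest H, ppm.
#' @param delta_Hprime Shift of the pure complex with guest H', ppm.
#' @return Ratio \[complex with H\] / \[complex with H'\].
#' @examples
#' bound_ratio_from_shift(-58.23, -57.94, -58.52)  # midpoint -> 1
#' @export
bound_ratio_from_shift <- function(delta_obs, delta_H, delta_Hprime) {
  if (delta_H == delta_Hprime) {
    stop("bound_ratio_from_shift: endpoint shifts are identical")
  }
  lo <- min(delta_H, delta_Hprime)
  hi <- max(delta_H, delta_Hprime)
  if (any(delta_obs <= lo) || any(delta_obs >= hi)) {
    stop("bound_ratio_from_shift: observed shift at or beyond an endpoint (degenerate ratio)")
  }
  (delta_obs - delta_Hprime) / (delta_H - delta_obs)
}

#' Competitive titration series
#'
#' One competition experiment between guests H and H': endpoint shifts of
#' the two pure complexes, pure-compound solubilities, and per-point molar
#' fractions with observed shifts.
#'
#' @param guest_H,guest_Hprime Guest ids.
#' @param delta_H,delta_Hprime Endpoint shifts (ppm) of the pure complexes;
#'   must differ.
#' @param S0_H,S0_Hprime Pure-compound aqueous solubilities, mol/L.
#' @param x_H Molar fractions of H in the excess hydrocarbon mixture, in
#'   (0, 1).
#' @param delta_obs Observed shifts, ppm, strictly between the endpoints.
#' @param x_Hprime Molar fractions of H'; defaults to `1 - x_H` and must
#'   satisfy `x_H + x_Hprime = 1` within 1e-9.
#' @return An object of class `titration_series`.
#' @seealso [fit_competition()], [simulate_titration()]
#' @export
titration_series <- function(guest_H, guest_Hprime, delta_H, delta_Hprime,
                             S0_H, S0_Hprime, x_H, delta_obs,
                             x_Hprime = 1 - x_H) {
  stopifnot(length(x_H) == length(delta_obs),
            length(x_H) == length(x_Hprime))
  if (delta_H == delta_Hprime) {
    stop("titration_series: endpoint shifts must differ")
  }
  if (any(abs(x_H + x_Hprime - 1) > 1e-9)) {
    stop("titration_series: x_H + x_Hprime must equal 1 within 1e-9")
  }
  if (any(x_H <= 0 | x_H >= 1)) {
    stop("titration_series: molar fractions must lie strictly in (0, 1)")
  }
  if (any(S0_H <= 0) || any(S0_Hprime <= 0)) {
    stop("titration_series: solubilities must be positive")
  }
  lo <- min(delta_H, delta_Hprime); hi <- max(delta_H, delta_Hprime)
  if (any(delta_obs <= lo | delta_obs >= hi)) {
    stop("titration_series: every observed shift must lie strictly between the endpoint shifts")
  }
  structure(
    list(guest_H = guest_H, guest_Hprime = guest_Hprime,
         delta_H = delta_H, delta_Hprime = delta_Hprime,
         S0_H = S0_H, S0_Hprime = S0_Hprime,
         points = data.frame(x_H = x_H, x_Hprime = x_Hprime,
                             delta_obs = delta_obs)),
    class = "titration_series"
  )
}

#' @export
print.titration_series <- function(x, ...) {
  cat(sprintf("Competitive titration %s vs %s: %d points\n", x$guest_H,
              x$guest_Hprime, nrow(x$points)))
  cat(sprintf("  endpoints %.3f / %.3f ppm; S0 %.3g / %.3g mol/L\n",
              x$delta_H, x$delta_Hprime, x$S0_H, x$S0_Hprime))
  invisible(x)
}

#' Fit a competitive titration
#'
#' Regresses the bound-complex ratio (from [bound_ratio_from_shift()])
#' against the free-solute concentration ratio
#' (x_H S0_H) / (x_H' S0_H'), with a free intercept to absorb mixture
#' non-ideality. The slope is the relative binding constant K_rel (H over
#' H'); the intercept is reported as a non-ideality diagnostic.
#'
#' The slope standard error (`K_rel_se`) propagates the shift noise through
#' the fast-exchange transform: the per-point variance of the ratio scales
#' as (delta_H - delta)^-4, so the plain homoscedastic OLS standard error
#' (also reported, as `se_ols`) badly understates the uncertainty of points
#' near the H endpoint. The shift-noise variance is estimated from the
#' shift-space residuals on n - 2 degrees of freedom.
#'
#' @param series A [titration_series()].
#' @param through_origin Also fit with the intercept forced to zero and
#'   report that slope (`K_rel_origin`) alongside the default.
#' @return An object of class `competition_fit` with elements `K_rel`,
#'   `K_rel_se`, `se_ols`, `intercept`, `intercept_se`, `r_squared`, `n`,
#'   `df`, `flagged` (TRUE if the fitted slope is non-positive), and
#'   `provenance` (the relay step "H/H'").
#' @examples
#' ts <- simulate_titration(true_K_rel = 10, noise_sd = 0, seed = 1)
#' fit_competition(ts)
#' @export
fit_competition <- function(series, through_origin = FALSE) {
  stopifnot(inherits(series, "titration_series"))
  pts <- series$points
  if (nrow(pts) < 3) stop("fit_competition: need at least 3 points")
  y <- bound_ratio_from_shift(pts$delta_obs, series$delta_H,
                              series$delta_Hprime)
  x <- mixture_solubility(pts$x_H, series$S0_H) /
    mixture_solubility(pts$x_Hprime, series$S0_Hprime)
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope <= 0) {
    warning("fit_competition: non-positive fitted slope; estimate flagged")
  }
  # shift-noise variance from residuals mapped back to the shift domain
  yhat <- stats::fitted(fit)
  dhat <- (yhat * series$delta_H + series$delta_Hprime) / (1 + yhat)
  s2_delta <- sum((pts$delta_obs - dhat)^2) / (nrow(pts) - 2)
  v_y <- s2_delta * (series$delta_H - series$delta_Hprime)^2 /
    (series$delta_H - pts$delta_obs)^4
  cx <- (x - mean(x)) / sum((x - mean(x))^2)
  se_prop <- sqrt(sum(cx^2 * v_y))
  out <- list(
    numerator_guest = series$guest_H,
    denominator_guest = series$guest_Hprime,
    K_rel = slope,
    K_rel_se = se_prop,
    se_ols = unname(sm$coefficients[2, 2]),
    intercept = unname(stats::coef(fit)[1]),
    intercept_se = unname(sm$coefficients[1, 2]),
    r_squared = sm$r.squared,
    n = nrow(pts),
    df = fit$df.residual,
    flagged = !is.finite(slope) || slope <= 0,
    provenance = paste0(series$guest_H, "/", series$guest_Hprime),
    lm = fit
  )
  if (through_origin) {
    fit0 <- stats::lm(y ~ x - 1)
    out$K_rel_origin <- unname(stats::coef(fit0)[1])
    out$K_rel_origin_se <- unname(summary(fit0)$coefficients[1, 2])
  }
  structure(out, class = "competition_fit")
}

#' @export
print.competition_fit <- function(x, ...) {
  cat(sprintf("Relative affinity K(%s / %s) = %.4g (+/- %.2g), n = %d\n",
              x$numerator_guest, x$denominator_guest, x$K_rel, x$K_rel_se,
              x$n))
  cat(sprintf("  intercept %.3g (+/- %.2g) [non-ideality diagnostic], R^2 = %.4f\n",
              x$intercept, x$intercept_se, x$r_squared))
  if (!is.null(x$K_rel_origin)) {
    cat(sprintf("  through-origin slope %.4g (+/- %.2g)\n", x$K_rel_origin,
                x$K_rel_origin_se))
  }
  if (x$flagged) cat("  WARNING: non-positive slope; estimate flagged\n")
  invisible(x)
}

#' @export
coef.competition_fit <- function(object, ...) {
  c(K_rel = object$K_rel, intercept = object$intercept)
}

#' @export
confint.competition_fit <- function(object, parm = "K_rel", level = 0.95, ...) {
  tq <- stats::qt(1 - (1 - level) / 2, object$df)
  ci <- c(object$K_rel - tq * object$K_rel_se,
          object$K_rel + tq * object$K_rel_se)
  names(ci) <- paste0(format(100 * c((1 - level) / 2, 1 - (1 - level) / 2)),
                      " %")
  ci
}

#' @export
summary.competition_fit <- function(object, ...) {
  print(object)
  invisible(object)
}

#' Chain relative affinities through relay guests
#'
#' Some guest pairs cannot be compared directly; their relative affinities
#' are chained through relay guests (K(A/C) = K(A/B) K(B/C)). Given a set of
#' measured pairwise affinities, rescales every guest to a common reference
#' by multiplying K values along the unique relay path, propagating standard
#' errors in log space and recording the path. Inconsistent cycles (redundant
#' measurements disagreeing by more than 3 combined sigma) are an error.
#'
#' @param measured List of [fit_competition()] results, or a data frame with
#'   columns `numerator_guest`, `denominator_guest`, `K_rel` and optionally
#'   `K_rel_se`.
#' @param target_reference Guest id all affinities are rescaled to.
#' @return Data frame with one row per guest: `guest`, `K_rel`, `K_rel_se`
#'   (relative to `target_reference`) and `provenance` (the relay path).
#' @examples
#' m <- data.frame(numerator_guest = c("a", "b"),
#'                 denominator_guest = c("b", "c"),
#'                 K_rel = c(2, 3), K_rel_se = c(0.1, 0.1))
#' chain_affinities(m, "c")   # K(a/c) = 6
#' @export
chain_affinities <- function(measured, target_reference) {
  if (is.list(measured) && !is.data.frame(measured) &&
      all(vapply(measured, inherits, logical(1), "competition_fit"))) {
    measured <- do.call(rbind, lapply(measured, function(m) {
      data.frame(numerator_guest = m$numerator_guest,
                 denominator_guest = m$denominator_guest,
                 K_rel = m$K_rel, K_rel_se = m$K_rel_se,
                 stringsAsFactors = FALSE)
    }))
  }
  stopifnot(is.data.frame(measured),
            all(c("numerator_guest", "denominator_guest", "K_rel") %in%
                  names(measured)))
  if (is.null(measured$K_rel_se)) measured$K_rel_se <- 0
  if (any(measured$K_rel <= 0)) {
    stop("chain_affinities: all measured K_rel must be positive")
  }
  guests <- unique(c(measured$numerator_guest, measured$denominator_guest))
  if (!target_reference %in% guests) {
    stop("chain_affinities: target reference '", target_reference,
         "' not among measured guests")
  }
  # log-space edge list (both directions)
  edges <- rbind(
    data.frame(from = measured$denominator_guest,
               to = measured$numerator_guest,
               logk = log(measured$K_rel),
               var = (measured$K_rel_se / measured$K_rel)^2,
               label = paste0(measured$numerator_guest, "/",
                              measured$denominator_guest),
               stringsAsFactors = FALSE),
    data.frame(from = measured$numerator_guest,
               to = measured$denominator_guest,
               logk = -log(measured$K_rel),
               var = (measured$K_rel_se / measured$K_rel)^2,
               label = paste0(measured$denominator_guest, "/",
                              measured$numerator_guest),
               stringsAsFactors = FALSE)
  )
  # BFS from the reference, accumulating log K and variance along the path
  logk <- stats::setNames(rep(NA_real_, length(guests)), guests)
  vark <- path <- logk
  logk[target_reference] <- 0
  vark[target_reference] <- 0
  path[target_reference] <- target_reference
  queue <- target_reference
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    out <- edges[edges$from == cur, , drop = FALSE]
    for (i in seq_len(nrow(out))) {
      nb <- out$to[i]
      cand_logk <- logk[cur] + out$logk[i]
      cand_var <- vark[cur] + out$var[i]
      if (is.na(logk[nb])) {
        logk[nb] <- cand_logk
        vark[nb] <- cand_var
        path[nb] <- paste(path[cur], out$label[i], sep = " -> ")
        queue <- c(queue, nb)
      } else {
        # redundant path: demand consistency within 3 combined sigma
        tol <- 3 * sqrt(cand_var + vark[nb])
        if (abs(cand_logk - logk[nb]) > max(tol, 1e-9)) {
          stop(sprintf(paste0("chain_affinities: inconsistent cycle at guest",
                              " '%s' (log-K mismatch %.3g > 3 sigma = %.3g);",
                              " paths: [%s] vs [%s]"),
                       nb, abs(cand_logk - logk[nb]), tol, path[nb],
                       paste(path[cur], out$label[i], sep = " -> ")))
        }
      }
    }
  }
  if (anyNA(logk)) {
    stop("chain_affinities: guest(s) not connected to the reference: ",
         paste(names(logk)[is.na(logk)], collapse = ", "))
  }
  res <- data.frame(
    guest = names(logk),
    K_rel = exp(unname(logk)),
    K_rel_se = exp(unname(logk)) * sqrt(unname(vark)),
    provenance = unname(path),
    stringsAsFactors = FALSE
  )
  res[order(match(res$guest, guests)), , drop = FALSE]
}
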