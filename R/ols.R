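#' Ordinary least squares of host energies on mimic energies
#'
#' Thin wrapper around [stats::lm()] returning the quantities the cavity
#' characterizations report: slope, intercept, their standard errors, R^2,
#' and named residuals. With `slope` supplied, only the intercept is fitted
#' (used for unity-slope outlier screens) and the slope standard error is
#' `NA`.
#'
#' @param x,y Equal-length numeric vectors (kcal/mol). `n >= 3` for standard
#'   errors; `n = 2` is permitted with undefined (NA) errors.
#' @param ids Optional names for the residuals (guest ids).
#' @param slope If non-`NULL`, fix the slope at this value and fit the
#'   intercept only.
#' @return Object of class `ols_fit`: list with `slope`, `slope_se`,
#'   `intercept`, `intercept_se`, `r_squared`, `sigma`, `n`, `residuals`
#'   (named), and the underlying `lm` fit.
#' @examples
#' f <- ols(1:5, 2 * (1:5) + 1)
#' f$slope; f$r_squared
#' @export
ols <- function(x, y, ids = NULL, slope = NULL) {
  if (length(x) != length(y)) stop("ols: x and y must have equal length")
  if (anyNA(x) || anyNA(y)) stop("ols: missing values in x or y")
  n <- length(x)
  if (n < 2) stop("ols: need at least 2 points")
  if (stats::var(x) == 0) stop("ols: zero variance in x")
  if (is.null(slope)) {
    fit <- stats::lm(y ~ x)
    sm <- suppressWarnings(summary(fit))
    co <- sm$coefficients
    out <- list(
      slope = unname(stats::coef(fit)[2]),
      slope_se = if (n > 2) unname(co[2, 2]) else NA_real_,
      intercept = unname(stats::coef(fit)[1]),
      intercept_se = if (n > 2) unname(co[1, 2]) else NA_real_,
      r_squared = sm$r.squared,
      sigma = if (n > 2) sm$sigma else NA_real_,
      n = n,
      residuals = stats::setNames(unname(stats::residuals(fit)), ids),
      fixed_slope = FALSE,
      lm = fit
    )
  } else {
    off <- y - slope * x
    fit <- stats::lm(off ~ 1)  # intercept-only
    res <- stats::setNames(unname(stats::residuals(fit)), ids)
    ss_tot <- sum((y - mean(y))^2)
    out <- list(
      slope = slope,
      slope_se = NA_real_,
      intercept = unname(stats::coef(fit)[1]),
      intercept_se = if (n > 2) unname(summary(fit)$coefficients[1, 2])
                     else NA_real_,
      r_squared = if (ss_tot > 0) 1 - sum(res^2) / ss_tot else NA_real_,
      sigma = if (n > 2) stats::sd(res) * sqrt((n - 1) / (n - 1)) else NA_real_,
      n = n,
      residuals = res,
      fixed_slope = TRUE,
      lm = fit
    )
  }
  structure(out, class = "ols_fit")
}

#' @export
print.ols_fit <- function(x, ...) {
  cat(sprintf("OLS fit (n = %d)%s\n", x$n,
              if (x$fixed_slope) " [slope fixed]" else ""))
  cat(sprintf("  slope     %8.4f  (se %s)\n", x$slope,
              ifelse(is.na(x$slope_se), "NA", sprintf("%.4f", x$slope_se))))
  cat(sprintf("  intercept %8.4f  (se %s)\n", x$intercept,
              ifelse(is.na(x$intercept_se), "NA",
                     sprintf("%.4f", x$intercept_se))))
  cat(sprintf("  R^2 = %.4f\n", x$r_squared))
  invisible(x)
}

#' @export
coef.ols_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
residuals.ols_fit <- function(object, ...) object$residuals

#' Studentized residuals of an OLS fit
#'
#' Externally studentized residuals for free fits; for fixed-slope fits the
#' residuals are scaled by their standard deviation (leverage is constant).
#'
#' @param fit An [ols()] result.
#' @return Named numeric vector.
#' @export
studentized_residuals <- function(fit) {
  stopifnot(inherits(fit, "ols_fit"))
  if (fit$fixed_slope) {
    r <- fit$residuals
    if (stats::sd(r) == 0) return(stats::setNames(rep(0, length(r)), names(r)))
    stats::setNames(as.numeric(scale(r)), names(r))
  } else {
    # an (essentially) exact fit carries no evidence of outlyingness;
    # guard before rstudent amplifies float-level residuals
    yscale <- max(1, abs(stats::fitted(fit$lm)))
    if (all(abs(fit$residuals) < 1e-10 * yscale)) {
      return(stats::setNames(rep(0, fit$n), names(fit$residuals)))
    }
    st <- suppressWarnings(stats::rstudent(fit$lm))
    st[!is.finite(st)] <- 0
    stats::setNames(unname(st), names(fit$residuals))
  }
}
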