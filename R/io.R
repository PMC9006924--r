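# Readers and writers for user-supplied guest tables and characterization
# reports. CSV columns may carry unit suffixes (volume_A3, alpha_A3); the
# JSON mirror carries an explicit units block.

.col_aliases <- c(volume_A3 = "volume", alpha_A3 = "alpha",
                  sigma_prime_A = "sigma_prime")
.guest_units <- c(volume = "A^3", sigma_prime = "A", alpha = "A^3",
                  solv = "kcal/mol", cav = "kcal/mol",
                  solubility_aq = "mol/L", vapor_pressure = "kPa")

.numeric_guest_cols <- function(df) {
  setdiff(names(df), c("id", "name"))
}

.validate_guests <- function(df, where = "guest table") {
  for (col in c("id", "name", "volume")) {
    if (!col %in% names(df)) {
      stop(where, ": missing required column '", col, "'")
    }
  }
  df$id <- as.character(df$id)
  if (anyDuplicated(df$id)) {
    stop(where, ": duplicate guest id(s): ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  }
  for (col in .numeric_guest_cols(df)) {
    if (!is.numeric(df[[col]])) {
      bad <- suppressWarnings(as.numeric(df[[col]]))
      if (any(is.na(bad) & !is.na(df[[col]]) & nzchar(trimws(df[[col]])))) {
        stop(where, ": non-numeric value in column '", col, "'")
      }
      df[[col]] <- bad
    }
  }
  if (any(!is.na(df$volume) & df$volume <= 0)) {
    stop(where, ": volume must be positive")
  }
  if (!"sigma_prime" %in% names(df)) {
    df$sigma_prime <- effective_diameter(df$volume)
  }
  df
}

#' Read a guest table from CSV or JSON
#'
#' Expected CSV columns: `id`, `name`, `volume_A3` (or `volume`), and
#' optionally `alpha_A3`/`alpha`, `sigma_prime_A`/`sigma_prime`,
#' `solv_<solvent>`, `cav_<solvent>`, `solubility_aq`, `vapor_pressure`.
#' Any further columns are kept as descriptors. Missing `sigma_prime` is
#' derived from the volume via [effective_diameter()]. The JSON layout is
#' `{"units": {...}, "guests": [...]}` as written by [write_guest_table()].
#'
#' @param path File path.
#' @param format `"csv"` or `"json"`; default inferred from the extension.
#' @return Guest data frame.
#' @examples
#' tmp <- tempfile(fileext = ".csv")
#' write_guest_table(cb_guests(), tmp)
#' g <- read_guest_table(tmp)
#' @export
read_guest_table <- function(path, format = NULL) {
  if (!file.exists(path)) stop("read_guest_table: no such file: ", path)
  if (is.null(format)) {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  format <- match.arg(format, c("csv", "json"))
  if (format == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          check.names = FALSE,
                          colClasses = c(id = "character"))
  } else {
    obj <- jsonlite::fromJSON(path)
    df <- as.data.frame(obj$guests, stringsAsFactors = FALSE)
    df$id <- as.character(df$id)
  }
  hit <- names(df) %in% names(.col_aliases)
  names(df)[hit] <- .col_aliases[names(df)[hit]]
  .validate_guests(df, where = paste0("read_guest_table(", basename(path), ")"))
}

#' Write a guest table to CSV or JSON
#'
#' @param guests Guest data frame.
#' @param path Output path.
#' @param format `"csv"` or `"json"`; default inferred from the extension.
#' @return Invisibly, `path`.
#' @export
write_guest_table <- function(guests, path, format = NULL) {
  stopifnot(is.data.frame(guests))
  if (is.null(format)) {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  format <- match.arg(format, c("csv", "json"))
  if (format == "csv") {
    utils::write.csv(guests, path, row.names = FALSE, na = "")
  } else {
    jsonlite::write_json(
      list(units = as.list(.guest_units), guests = guests),
      path, auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
  }
  invisible(path)
}

.report_list <- function(x) {
  if (inherits(x, "cavity_fit")) {
    fit <- x$fit
    mim <- if (inherits(x$mimic, "solvent_model")) x$mimic$name else {
      paste(sprintf("%s:%g", vapply(x$mimic$solvents, `[[`, character(1),
                                    "name"), x$mimic$fractions),
            collapse = "+")
    }
    header <- list(host = x$host$host, mimic = mim,
                   reference_guest = x$reference_guest)
    exclusions <- x$excluded
  } else if (inherits(x, "ols_fit")) {
    fit <- x
    header <- list()
    exclusions <- character()
  } else {
    stop("write_report: expected a cavity_fit or ols_fit")
  }
  res <- as.list(fit$residuals)
  res <- res[order(names(res))]
  c(header,
    list(slope = fit$slope, slope_se = fit$slope_se,
         intercept = fit$intercept, intercept_se = fit$intercept_se,
         r_squared = fit$r_squared, n = fit$n,
         exclusions = as.list(exclusions),
         residuals = res))
}

#' Write a characterization report
#'
#' Machine-readable summary of a fit: slope, intercept, standard errors,
#' R^2, n, exclusions and per-guest residuals, with deterministic key
#' ordering. JSON round-trips through [read_report()]; the CSV layout is
#' two columns, `key` and `value`, residuals keyed `residual_<id>`.
#'
#' @param x A `cavity_fit` or [ols()] result.
#' @param path Output path.
#' @param format `"json"` or `"csv"`; default inferred from the extension.
#' @return Invisibly, `path`.
#' @examples
#' cf <- characterize_cavity(cb_host("CB6"), mimic = cb_solvents()$pfh)
#' tmp <- tempfile(fileext = ".json")
#' write_report(cf, tmp)
#' read_report(tmp)$slope
#' @export
write_report <- function(x, path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "json"
  }
  format <- match.arg(format, c("json", "csv"))
  rep <- .report_list(x)
  if (format == "json") {
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
  } else {
    flat <- rep
    flat$residuals <- NULL
    flat$exclusions <- paste(unlist(rep$exclusions), collapse = ";")
    rows <- data.frame(key = names(flat),
                       value = vapply(flat, function(v)
                         if (is.numeric(v)) format(v, digits = 15)
                         else as.character(v), character(1)),
                       stringsAsFactors = FALSE)
    res <- rep$residuals
    if (length(res)) {
      rows <- rbind(rows, data.frame(
        key = paste0("residual_", names(res)),
        value = vapply(res, function(v) format(v, digits = 15), character(1)),
        stringsAsFactors = FALSE))
    }
    utils::write.csv(rows, path, row.names = FALSE)
  }
  invisible(path)
}

#' Read back a JSON characterization report
#'
#' @param path Path to a JSON file written by [write_report()].
#' @return Named list mirroring the report structure.
#' @export
read_report <- function(path) {
  if (!file.exists(path)) stop("read_report: no such file: ", path)
  obj <- jsonlite::fromJSON(path)
  obj$exclusions <- as.character(unlist(obj$exclusions))
  obj$residuals <- unlist(obj$residuals)
  obj
}
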