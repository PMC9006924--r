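#' Host transfer-energy dataset
#'
#' Bundles a host (a cucurbituril or a CB\[8\]/auxiliary-probe cavity) with
#' its per-guest gas->cavity transfer free energies, either absolute or
#' relative to a named reference guest, plus optional uncertainties and a
#' curated list of excluded guests (with the reason each is excluded, e.g.
#' "too large to fit").
#'
#' @param host Host label, e.g. `"CB6"` or `"CB8.P3"`.
#' @param transfer Named numeric vector: guest id -> transfer free energy in
#'   kcal/mol (negative = favorable).
#' @param reference_guest Guest id the energies are normalized to, or
#'   `"absolute"`. If relative, the reference guest's own entry must be 0.
#' @param uncertainties Optional named numeric vector (kcal/mol, 1 sigma).
#' @param exclusions Optional data frame with columns `id` and `reason`
#'   flagging curated outliers.
#' @return An object of class `host_data`.
#' @examples
#' host_data("toy", c(a = -1, b = 0, c = 2), reference_guest = "b")
#' @seealso [cb_host()] for the packaged datasets.
#' @export
host_data <- function(host, transfer, reference_guest = "absolute",
                      uncertainties = NULL, exclusions = NULL) {
  stopifnot(is.character(host), length(host) == 1L)
  if (!is.numeric(transfer) || is.null(names(transfer)) ||
      any(!nzchar(names(transfer)))) {
    stop("host_data: transfer must be a named numeric vector (guest id -> kcal/mol)")
  }
  if (anyDuplicated(names(transfer))) {
    stop("host_data: duplicate guest ids in transfer")
  }
  if (!identical(reference_guest, "absolute")) {
    if (!reference_guest %in% names(transfer)) {
      stop("host_data: reference guest '", reference_guest,
           "' absent from transfer map")
    }
    if (transfer[[reference_guest]] != 0) {
      stop("host_data: relative dataset must have transfer[reference] == 0")
    }
  }
  if (!is.null(uncertainties)) {
    stopifnot(is.numeric(uncertainties), !is.null(names(uncertainties)))
    if (!all(names(uncertainties) %in% names(transfer))) {
      stop("host_data: uncertainties for unknown guest ids")
    }
  }
  if (is.null(exclusions)) {
    exclusions <- data.frame(id = character(), reason = character(),
                             stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(exclusions), all(c("id", "reason") %in% names(exclusions)))
  structure(
    list(host = host, transfer = transfer, reference_guest = reference_guest,
         uncertainties = uncertainties, exclusions = exclusions),
    class = "host_data"
  )
}

#' @export
print.host_data <- function(x, ...) {
  cat(sprintf("Host dataset '%s': %d guests, %s energies\n", x$host,
              length(x$transfer),
              if (identical(x$reference_guest, "absolute")) "absolute"
              else paste0("relative to guest ", x$reference_guest)))
  if (nrow(x$exclusions)) {
    cat("  curated exclusions:",
        paste(sprintf("%s (%s)", x$exclusions$id, x$exclusions$reason),
              collapse = "; "), "\n")
  }
  invisible(x)
}

.excl_df <- function(ids, reasons) {
  data.frame(id = ids, reason = reasons, stringsAsFactors = FALSE)
}

#' Packaged host datasets
#'
#' Gas->cavity transfer free energies for the six cavities studied with the
#' pre-formed cavity model, assembled from the packaged tables:
#' \describe{
#'   \item{`CB5`}{Noble gases He-Xe plus methane and ethane, absolute;
#'     ethane is curated out as too large to fit.}
#'   \item{`CB6`}{7 hydrocarbons, absolute.}
#'   \item{`CB7`}{15 rigid hydrocarbons, absolute; methane is curated out
#'     (suspected to bind as a dimer).}
#'   \item{`CB8.P2`}{13 hydrocarbons, absolute; cyclohexane and cyclopentane
#'     (too large to fit), methane (binds as a dimer) and isobutane
#'     (weaker than expected, unexplained) are curated out.}
#'   \item{`CB8.P1`, `CB8.P3`}{9 rigid hydrocarbons, relative to benzene.}
#' }
#'
#' @param host One of `"CB5"`, `"CB6"`, `"CB7"`, `"CB8.P1"`, `"CB8.P2"`,
#'   `"CB8.P3"`.
#' @return A [host_data()] object.
#' @examples
#' cb_host("CB6")
#' @export
cb_host <- function(host = c("CB5", "CB6", "CB7", "CB8.P1", "CB8.P2",
                             "CB8.P3")) {
  host <- match.arg(host)
  t1 <- .affinity_table()
  t2 <- .hydrocarbon_table()
  t3 <- .noblegas_table()
  pick <- function(df, col) {
    keep <- !is.na(df[[col]])
    stats::setNames(df[[col]][keep], df$id[keep])
  }
  switch(host,
    CB5 = host_data("CB5", pick(t3, "CB5"),
                    exclusions = .excl_df("2", "too large to fit")),
    CB6 = host_data("CB6", pick(t2, "CB6")),
    CB7 = host_data("CB7", pick(t2, "CB7"),
                    exclusions = .excl_df("1", "suspected to bind as a dimer")),
    CB8.P2 = host_data("CB8.P2", pick(t2, "CB8.P2"),
                       exclusions = .excl_df(
                         c("14", "12", "1", "9"),
                         c("too large to fit", "too large to fit",
                           "binds as a dimer",
                           "weaker than expected (unexplained)"))),
    CB8.P1 = host_data("CB8.P1", pick(t1, "ddG_gas_P1"),
                       reference_guest = "18"),
    CB8.P3 = host_data("CB8.P3", pick(t1, "ddG_gas_P3"),
                       reference_guest = "18",
                       uncertainties = pick(t1, "ddG_aq_P3_se"))
  )
}
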