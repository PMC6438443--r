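#' Spatiotemporal panel of annual time series
#'
#' Construct a validated panel of `N` location time series of equal length
#' `T` on an annual grid. This is the basic data container of the package:
#' rows are locations, columns are years.
#'
#' @param values Numeric matrix, `N` locations by `T` years. All entries
#'   must be finite; missing data are rejected at construction.
#' @param location_ids Character vector of `N` unique location labels.
#'   Defaults to the row names of `values`, or `"loc1"`, ... if absent.
#' @param years Strictly increasing integer vector of length `T` with step
#'   1. Defaults to the column names of `values`, or `1, ..., T`.
#'
#' @return An object of class `"st_panel"`: a list with elements `values`
#'   (the matrix, with `location_ids` as row names and `years` as column
#'   names), `location_ids`, and `years`.
#'
#' @examples
#' p <- st_panel(matrix(rnorm(3 * 10), 3, 10))
#' dim(p$values)
#' @export
st_panel <- function(values, location_ids = NULL, years = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (locations x years)")
  }
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)
    stop(sprintf(
      "non-finite values in panel, e.g. at location row %d, time column %d",
      bad[1, 1], bad[1, 2]
    ))
  }
  n <- nrow(values)
  tt <- ncol(values)
  if (n < 2) stop("panel needs at least 2 locations")
  if (tt < 4) stop("panel needs at least 4 time steps")
  if (is.null(location_ids)) {
    location_ids <- rownames(values)
    if (is.null(location_ids)) location_ids <- paste0("loc", seq_len(n))
  }
  location_ids <- as.character(location_ids)
  if (length(location_ids) != n) stop("`location_ids` must have one entry per row")
  if (anyDuplicated(location_ids)) stop("duplicate location ids")
  if (is.null(years)) {
    years <- suppressWarnings(as.integer(colnames(values)))
    if (is.null(colnames(values)) || anyNA(years)) years <- seq_len(tt)
  }
  years <- as.integer(years)
  if (length(years) != tt) stop("`years` must have one entry per column")
  if (anyNA(years) || any(diff(years) != 1L)) {
    stop("`years` must be strictly increasing integers with step 1")
  }
  dimnames(values) <- list(location_ids, years)
  structure(
    list(values = values, location_ids = location_ids, years = years),
    class = "st_panel"
  )
}

#' @export
print.st_panel <- function(x, ...) {
  cat(sprintf(
    "<st_panel> %d locations x %d years (%d-%d)\n",
    nrow(x$values), ncol(x$values), x$years[1], x$years[length(x$years)]
  ))
  invisible(x)
}

#' @export
dim.st_panel <- function(x) dim(x$values)

#' @export
as.matrix.st_panel <- function(x, ...) x$values

#' Panel in long (tidy) form
#'
#' @param x An `st_panel`.
#' @param ... Unused.
#' @return A data frame with columns `location`, `year`, `value`.
#' @export
tidy.st_panel <- function(x, ...) {
  data.frame(
    location = rep(x$location_ids, times = length(x$years)),
    year = rep(x$years, each = length(x$location_ids)),
    value = as.vector(x$values),
    stringsAsFactors = FALSE
  )
}

stopifnot_panel <- function(x) {
  if (!inherits(x, "st_panel")) stop("expected an `st_panel` object")
  invisible(x)
}
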