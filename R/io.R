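#' Read a spatiotemporal panel from CSV
#'
#' Expected layout: a header row of integer years, first column holding
#' location ids, one row per location. Duplicate location ids, ragged
#' rows, missing or non-numeric cells are rejected with informative
#' errors.
#'
#' @param path Path to the CSV file.
#' @return An [st_panel()].
#' @export
read_panel_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (ncol(raw) < 2) stop("panel CSV needs a location column plus year columns")
  ids <- raw[[1]]
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate location label: '%s'", ids[duplicated(ids)][1]))
  }
  years <- suppressWarnings(as.integer(colnames(raw)[-1]))
  if (anyNA(years)) stop("header must contain integer years")
  cells <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(apply(cells, 2, as.numeric))
  num <- matrix(num, nrow = nrow(raw))
  if (anyNA(num) || any(cells == "")) {
    bad <- which(is.na(num) | cells == "", arr.ind = TRUE)
    stop(sprintf(
      "missing or non-numeric cell(s), e.g. location '%s', year %d",
      ids[bad[1, 1]], years[bad[1, 2]]
    ))
  }
  st_panel(num, ids, years)
}

#' Write a spatiotemporal panel to CSV
#'
#' Inverse of [read_panel_csv()].
#'
#' @param panel An [st_panel()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_panel_csv <- function(panel, path) {
  stopifnot_panel(panel)
  df <- data.frame(location = panel$location_ids,
                   panel$values, check.names = FALSE)
  colnames(df) <- c("location", panel$years)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a mean-field magnitude surface to CSV
#'
#' Rows are timescales (first column, formatted to 6 decimals), columns
#' are years, values are magnitudes. Reading the file back reproduces the
#' magnitudes to 1e-12.
#'
#' @param surface A `"mean_field"`.
#' @param path Output file path.
#' @param years Optional year labels for the columns.
#' @return `path`, invisibly.
#' @export
write_surface_csv <- function(surface, path, years = NULL) {
  if (!inherits(surface, "mean_field")) stop("expected a `mean_field`")
  mag <- t(Mod(surface$values))            # timescale x year
  if (is.null(years)) years <- seq_len(ncol(mag))
  df <- data.frame(timescale = sprintf("%.6f", surface$timescales), mag,
                   check.names = FALSE)
  colnames(df) <- c("timescale", years)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a magnitude surface written by [write_surface_csv()]
#'
#' @param path Path to the CSV file.
#' @return List with `timescales` and `values` (timescale x year matrix).
#' @export
read_surface_csv <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE)
  list(
    timescales = as.numeric(raw[[1]]),
    values = as.matrix(raw[, -1, drop = FALSE])
  )
}

#' Write a transform set to a directory of per-timescale CSV pairs
#'
#' One `real` and one `imag` CSV per timescale (panel layout), plus a
#' JSON sidecar recording the grid and central frequency.
#'
#' @param transforms A `"wavelet_set"` or `"normalized_set"`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_transforms_dir <- function(transforms, dir) {
  if (!inherits(transforms, c("wavelet_set", "normalized_set"))) {
    stop("expected a transform set")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  panel <- transforms$series
  for (j in seq_along(transforms$timescales)) {
    for (part in c("real", "imag")) {
      vals <- if (part == "real") Re(transforms$coefficients[, , j]) else
        Im(transforms$coefficients[, , j])
      p <- st_panel(vals, panel$location_ids, panel$years)
      write_panel_csv(p, file.path(dir, sprintf("sigma_%03d_%s.csv", j, part)))
    }
  }
  side <- list(
    timescales = transforms$timescales, f0 = transforms$f0,
    normalization = if (is.null(transforms$normalization)) "none" else
      transforms$normalization
  )
  jsonlite::write_json(side, file.path(dir, "grid.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
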