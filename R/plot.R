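#' Heatmap of a mean-field surface
#'
#' Time-by-timescale heatmap of the magnitude of a wavelet (phasor) mean
#' field, with the timescale axis on a log scale, optionally overlaid
#' with phase-synchrony significance contours from [wpmf_thresholds()].
#'
#' @param object A `"mean_field"`.
#' @param thresholds Optional `"wpmf_thresholds"` object; its levels are
#'   drawn as contours of the magnitude surface (meaningful mainly for
#'   WPMF surfaces).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mean_field <- function(object, thresholds = NULL, ...) {
  df <- tidy.mean_field(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = time_index, y = timescale, fill = magnitude
  )) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_log10() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(
      x = "time", y = "timescale (years)",
      fill = paste0("|", object$kind, "|"),
      title = sprintf("%s magnitude", toupper(object$kind))
    )
  if (!is.null(thresholds)) {
    p <- p + ggplot2::geom_contour(
      ggplot2::aes(z = magnitude),
      breaks = thresholds$thresholds, colour = "white", linewidth = 0.3
    )
  }
  p
}

#' Coherence profile plot
#'
#' Coherence against timescale, with surrogate quantile curves when
#' present.
#'
#' @param object A `"coherence"` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.coherence <- function(object, ...) {
  df <- tidy.coherence(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = timescale, y = coherence)) +
    ggplot2::geom_line(colour = "red") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "timescale (years)", y = "spatial coherence")
  qcols <- grep("^q", names(df), value = TRUE)
  for (qc in qcols) {
    p <- p + ggplot2::geom_line(ggplot2::aes(y = !!as.name(qc)),
                                linetype = "dashed", colour = "grey30")
  }
  p
}

#' Synchrony partition bar plot
#'
#' @param object A `"synchrony_partition"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.synchrony_partition <- function(object, ...) {
  df <- tidy.synchrony_partition(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(component, fraction), y = fraction
  )) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "fraction of observed band synchrony")
}
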