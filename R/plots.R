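# ggplot2 graphics for the main result types.

#' Length-coverage scatter of classified contigs
#'
#' Log-log scatter of contig length against coverage, coloured by
#' circularity -- the standard view for spotting the high-coverage long-circle
#' pool in an assembly.
#'
#' @param contigs Tibble from [detect_circles] with a `coverage` column.
#' @return A ggplot object.
#' @export
plot_circle_scatter <- function(contigs) {
  stopifnot(all(c("length", "coverage", "is_circular") %in% names(contigs)))
  ggplot2::ggplot(contigs,
                  ggplot2::aes(x = .data$length, y = .data$coverage,
                               colour = .data$is_circular)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "contig length (bp)", y = "coverage",
                  colour = "circular") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.peak_spacing <- function(object, ...) {
  ggplot2::ggplot(object$density, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$peaks, linetype = "dashed",
                        colour = "red", alpha = 0.5) +
    ggplot2::labs(x = "trimmed circle length (bp)", y = "density",
                  subtitle = if (is.na(object$spacing)) "spacing undefined" else
                    sprintf("mean adjacent-peak spacing %.2f bp", object$spacing)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.circle_families <- function(object, ...) {
  ggplot2::ggplot(object$size_histogram,
                  ggplot2::aes(x = .data$family_size, y = .data$n)) +
    ggplot2::geom_col() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "family size (members)", y = "number of families") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.q_selection <- function(object, ...) {
  ggplot2::ggplot(object$report,
                  ggplot2::aes(x = .data$flagged_fraction,
                               fill = .data$selected)) +
    ggplot2::geom_histogram(bins = 30, boundary = 0) +
    ggplot2::geom_vline(xintercept = object$min_fraction, linetype = "dashed") +
    ggplot2::labs(x = sprintf("fraction of positions with q > %.2g", object$q_cut),
                  y = "partitions", fill = "selected") +
    ggplot2::theme_minimal()
}

#' RCFV distribution across partitions
#'
#' @param report The `report` tibble from [rcfv_filter].
#' @param rcfv_max The cutoff to mark.
#' @return A ggplot object.
#' @export
plot_rcfv <- function(report, rcfv_max = 0.115) {
  ggplot2::ggplot(report, ggplot2::aes(x = .data$rcfv, fill = .data$kept)) +
    ggplot2::geom_histogram(bins = 30, boundary = 0) +
    ggplot2::geom_vline(xintercept = rcfv_max, linetype = "dashed") +
    ggplot2::labs(x = "partition RCFV", y = "partitions", fill = "kept") +
    ggplot2::theme_minimal()
}
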