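#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.hic_decay <- function(object, ...) {
  ggplot2::ggplot(object[object$count > 0, ],
                  ggplot2::aes(x = .data$distance, y = .data$prob)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "genomic separation (bp)", y = "contact probability",
                  title = "Contact decay curve") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.hic_insulation <- function(object, boundaries = NULL, ...) {
  p <- ggplot2::ggplot(object[object$valid, ],
                       ggplot2::aes(x = (.data$start + .data$end) / 2,
                                    y = .data$score)) +
    ggplot2::geom_line(colour = "grey30", linewidth = 0.3) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = "insulation (log2)",
                  title = "Insulation score") +
    ggplot2::theme_minimal()
  if (!is.null(boundaries) && nrow(boundaries)) {
    p <- p + ggplot2::geom_vline(
      data = boundaries,
      ggplot2::aes(xintercept = (.data$start + .data$end) / 2),
      linetype = "dashed", colour = "grey60", linewidth = 0.2)
  }
  p
}

#' @export
autoplot.hic_aca <- function(object, ...) {
  df <- tidy.hic_aca(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$slot1, .data$slot2,
                                   fill = log1p(.data$value))) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "log1p signal") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "isochromosome slot", y = "isochromosome slot",
                  title = "Aggregate chromosome analysis") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.hic_structure <- function(object, ...) {
  co <- object$coords[object$embedded, ]
  ggplot2::ggplot(co, ggplot2::aes(.data$x, .data$y, colour = .data$chrom)) +
    ggplot2::geom_path(linewidth = 0.4) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = "3D genome model (xy projection)") +
    ggplot2::theme_minimal()
}
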