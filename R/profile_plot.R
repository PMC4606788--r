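#' Colour map for mitochondrial mass classes
#'
#' very low: blue, low: light blue, normal: light orange, high: orange,
#' very high: red.
#' @keywords internal
PORIN_COLOURS <- c(very_low = "#2166AC", low = "#92C5DE",
                   normal = "#FDBF6F", high = "#FF7F00",
                   very_high = "#E31A1C")

PROTEIN_BAND_COLOURS <- c(normal = "#EFDFC0", int_plus = "#F7EFDD",
                          int_minus = "#BFD8E8", deficient = "#4393C3")

#' 2D mitochondrial expression-profile plot
#'
#' The per-fibre OXPHOS profile: NDUFB8 (complex I) on the x axis, COX-I
#' (complex IV) on the y axis, one dot per fibre colour-coded by its
#' mitochondrial mass (porin) class. Thin dashed lines mark the SD
#' classification limits on both axes, bold dashed lines the mean
#' expression of protein-normal fibres, and rails along each axis mark the
#' category bands. Default axes are Z-scores (straight category
#' boundaries); transformed log-signal axes are available via `axes`.
#'
#' @param classified classified fibre table from [classify_section()].
#' @param thresholds the [classification_thresholds()] used.
#' @param axes `"z"` (Z-scores) or `"transformed"` (log signal `_T`).
#' @param title plot title; fibre count is appended.
#' @return a ggplot object (regenerable from the classified table alone).
#' @export
make_profile_plot <- function(classified,
                              thresholds = classification_thresholds(),
                              axes = c("z", "transformed"),
                              title = "OXPHOS expression profile") {
  axes <- match.arg(axes)
  if (nrow(classified) == 0) stop_input("classified table is empty")
  if (axes == "z") {
    xcol <- "ndufb8_z"; ycol <- "coxi_z"
    xlab <- "NDUFB8_Z (complex I)"; ylab <- "COX-I_Z (complex IV)"
  } else {
    xcol <- "ndufb8_T"; ycol <- "coxi_T"
    xlab <- "ODNDUFB8_T"; ylab <- "ODCOX-I_T"
  }
  df <- data.frame(x = classified[[xcol]], y = classified[[ycol]],
                   porin_class = factor(as.character(classified$porin_class),
                                        levels = PORIN_CLASSES),
                   coxi_class = classified$coxi_class,
                   ndufb8_class = classified$ndufb8_class)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                        colour = .data$porin_class)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.8) +
    ggplot2::scale_colour_manual(values = PORIN_COLOURS, drop = FALSE,
                                 name = "mitochondrial mass") +
    ggplot2::labs(x = xlab, y = ylab,
                  title = sprintf("%s (n = %d fibres)", title, nrow(df))) +
    ggplot2::theme_bw()
  if (axes == "z") {
    cuts <- thresholds$protein_cuts
    p <- p +
      ggplot2::geom_vline(xintercept = cuts, linetype = "dashed",
                          linewidth = 0.3, colour = "black") +
      ggplot2::geom_hline(yintercept = cuts, linetype = "dashed",
                          linewidth = 0.3, colour = "black")
    # bold dashed lines: mean expression of protein-normal fibres
    nx <- mean(df$x[df$ndufb8_class == "normal"])
    ny <- mean(df$y[df$coxi_class == "normal"])
    if (is.finite(nx)) {
      p <- p + ggplot2::geom_vline(xintercept = nx, linetype = "dashed",
                                   linewidth = 0.9, colour = "black")
    }
    if (is.finite(ny)) {
      p <- p + ggplot2::geom_hline(yintercept = ny, linetype = "dashed",
                                   linewidth = 0.9, colour = "black")
    }
    # axis rails marking the category bands
    rng_x <- range(df$x, cuts)
    rng_y <- range(df$y, cuts)
    pad_x <- 0.03 * diff(rng_x)
    pad_y <- 0.03 * diff(rng_y)
    band_edges <- function(rng) {
      data.frame(
        from = c(rng[1] - 0.5, cuts[3], cuts[2], cuts[1]),
        to = c(cuts[3], cuts[2], cuts[1], rng[2] + 0.5),
        band = factor(c("deficient", "int_minus", "int_plus", "normal"),
                      levels = PROTEIN_CLASSES)
      )
    }
    bx <- band_edges(rng_x)
    by <- band_edges(rng_y)
    p <- p +
      ggplot2::annotate("segment",
                        x = bx$from, xend = bx$to,
                        y = rng_y[1] - pad_y, yend = rng_y[1] - pad_y,
                        colour = PROTEIN_BAND_COLOURS[as.character(bx$band)],
                        linewidth = 2) +
      ggplot2::annotate("segment",
                        x = rng_x[1] - pad_x, xend = rng_x[1] - pad_x,
                        y = by$from, yend = by$to,
                        colour = PROTEIN_BAND_COLOURS[as.character(by$band)],
                        linewidth = 2)
  }
  p
}

#' Save a profile plot to file
#'
#' @param plot a ggplot from [make_profile_plot()].
#' @param path output path; format follows the extension (pdf/png/svg).
#' @param width,height device size in inches.
#' @param dpi raster resolution.
#' @export
save_profile_plot <- function(plot, path, width = 7, height = 6, dpi = 150) {
  ggplot2::ggsave(path, plot, width = width, height = height, dpi = dpi)
  invisible(path)
}
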