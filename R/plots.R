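# Base-graphics summaries of the typology and its spatial distribution.

#' Bar chart of the asynchrony type distribution
#'
#' @param dist A [type_distribution()] result.
#' @param ... Passed to [graphics::barplot()].
#' @return The bar midpoints, invisibly.
#' @export
plot_type_distribution <- function(dist, ...) {
  stopifnot(inherits(dist, "binoc_type_distribution"))
  graphics::barplot(100 * dist$proportions, ylab = "% of binocular fixations",
                    xlab = "asynchrony type", ...)
}

#' Plot a hexbin grid as shaded hexagons
#'
#' @param grid A [hexbin_counts()] result.
#' @param screen Optional [screen_geometry()] fixing the plot limits (drawn
#'   with the y axis pointing down, as in tracker coordinates).
#' @param ... Passed to [graphics::plot()].
#' @return `grid`, invisibly.
#' @export
plot_hexbin <- function(grid, screen = NULL, ...) {
  stopifnot(inherits(grid, "hexbin_grid"))
  r <- attr(grid, "hex_radius_px")
  xlim <- if (is.null(screen)) range(grid$cx) + c(-r, r) else
    c(0, screen$width_px)
  ylim <- if (is.null(screen)) rev(range(grid$cy) + c(-r, r)) else
    c(screen$height_px, 0)
  graphics::plot(NA, xlim = xlim, ylim = ylim, xlab = "x (px)",
                 ylab = "y (px)", asp = 1, ...)
  shade <- grDevices::gray(1 - 0.9 * grid$count / max(grid$count))
  ang <- pi / 6 + seq(0, 5) * pi / 3
  for (i in seq_len(nrow(grid))) {
    graphics::polygon(grid$cx[i] + r * cos(ang), grid$cy[i] + r * sin(ang),
                      col = shade[i], border = "grey40")
  }
  invisible(grid)
}
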