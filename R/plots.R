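#' Plot a labelled point cloud
#'
#' Vessels as magenta crosses, tumour cells dark red, stroma grey, necrotic
#' cells black; macrophages are coloured by phenotype from blue (M1, p = 0)
#' to yellow (M2, p = 1).
#'
#' @param x A [point_cloud()].
#' @param cex Point size.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.point_cloud <- function(x, cex = 0.6, ...) {
  p <- x$points
  d <- x$domain
  graphics::plot(NA, xlim = c(d$xmin, d$xmax), ylim = c(d$ymin, d$ymax),
                 xlab = "x (cell diameters)", ylab = "y (cell diameters)",
                 asp = 1, ...)
  base_col <- c(S = "grey70", T = "firebrick", N = "black")
  for (q in names(base_col)) {
    sel <- p$category == q
    if (any(sel)) graphics::points(p$x[sel], p$y[sel], pch = 16,
                                   cex = cex, col = base_col[[q]])
  }
  mac <- p$category == "M"
  if (any(mac)) {
    pal <- grDevices::hcl.colors(101, "Viridis")
    idx <- pmin(pmax(round(p$mark[mac] * 100) + 1, 1), 101)
    graphics::points(p$x[mac], p$y[mac], pch = 16, cex = cex, col = pal[idx])
  }
  ves <- p$category == "B"
  if (any(ves)) graphics::points(p$x[ves], p$y[ves], pch = 4, cex = cex * 1.6,
                                 col = "magenta", lwd = 2)
  invisible(x)
}

#' Plot a cross-PCF curve
#'
#' @param x A [cross_pcf()] result.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.cross_pcf <- function(x, ...) {
  graphics::plot(x$binning$r_mid, x$values, type = "l", lwd = 2,
                 xlab = "r (cell diameters)",
                 ylab = sprintf("g_%s%s(r)", x$source, x$target), ...)
  graphics::abline(h = 1, lty = 2, col = "grey50")
  invisible(x)
}

#' Heatmap of a wPCF surface
#'
#' Target mark `P` on the vertical axis, distance `r` on the horizontal axis,
#' colour-coded wPCF value centred on 1 (no correlation). Undefined rows are
#' left blank.
#'
#' @param x A [wpcf()] result.
#' @param zmax Colour-scale ceiling (values are truncated for display).
#' @param ... Passed to [graphics::image()].
#' @return Invisibly, `x`.
#' @export
plot.wpcf_surface <- function(x, zmax = NULL, ...) {
  z <- t(x$values)  # image() wants x along rows: r horizontal, P vertical
  if (is.null(zmax)) zmax <- max(2, stats::quantile(z, 0.98, na.rm = TRUE))
  z <- pmin(z, zmax)
  graphics::image(x = x$binning$r_mid, y = x$p_grid, z = z,
                  col = grDevices::hcl.colors(64, "RdYlBu", rev = TRUE),
                  xlab = "r (cell diameters)", ylab = "target mark P",
                  zlim = c(0, zmax), ...)
  invisible(x)
}
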