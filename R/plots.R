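#' Bivariate morphospace plot
#'
#' Scatter of two PC scores with glyphs by ecology bin: filled circles for
#' arboreal/scansorial, filled triangles for terrestrial/bipedal saltating,
#' red stars for fossils, open squares for unassigned extant taxa. Axis
#' labels carry each component's variance fraction.
#'
#' @param pca A [pca_result].
#' @param metadata Metadata data.frame covering the scored specimens.
#' @param axes Length-2 integer vector of PC indices (default PC1 vs PC2).
#' @param label_fossils If `TRUE`, fossil points are labelled with their ids.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the plotted score matrix.
#' @export
plot_morphospace <- function(pca, metadata, axes = c(1L, 2L),
                             label_fossils = TRUE, ...) {
  stopifnot(inherits(pca, "pca_result"), length(axes) == 2L)
  sc <- pca$scores[, axes, drop = FALSE]
  md <- metadata[match(pca$ids, metadata$specimen_id), , drop = FALSE]
  grp <- ifelse(md$is_fossil, "fossil", md$ecology_bin)
  pch <- c(arboreal_scansorial = 19, terrestrial_saltating = 17,
           unassigned = 22, fossil = 8)[grp]
  col <- c(arboreal_scansorial = "forestgreen", terrestrial_saltating = "grey30",
           unassigned = "purple", fossil = "red")[grp]
  lab <- sprintf("PC%d (%.1f%%)", axes, 100 * pca$variance_fraction[axes])
  graphics::plot(sc, pch = pch, col = col, xlab = lab[1], ylab = lab[2], ...)
  graphics::abline(h = 0, v = 0, col = "grey85", lty = 3)
  if (label_fossils && any(md$is_fossil)) {
    graphics::text(sc[md$is_fossil, , drop = FALSE],
                   labels = pca$ids[md$is_fossil], pos = 3, cex = 0.7, col = "red")
  }
  invisible(sc)
}

#' @describeIn deformation_grid Draw a deformation grid with the
#'   reconstructed configuration overlaid.
#' @param x A `deformation_grid` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.deformation_grid <- function(x, ...) {
  g <- x$grid
  graphics::plot(g, type = "n", asp = 1, xlab = "", ylab = "",
                 main = sprintf("PC%d, score %.3g", x$axis, x$score), ...)
  for (i in seq_len(x$ny)) {
    rows <- ((i - 1) * x$nx + 1):(i * x$nx)
    graphics::lines(g[rows, 1], g[rows, 2], col = "grey60")
  }
  for (j in seq_len(x$nx)) {
    cols <- seq(j, x$nx * x$ny, by = x$nx)
    graphics::lines(g[cols, 1], g[cols, 2], col = "grey60")
  }
  graphics::points(x$shape, pch = 19, cex = 0.6)
  invisible(x)
}
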