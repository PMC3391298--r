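#' FDR-coloured ROC plot with the FCAUC region shaded
#'
#' Draws the empirical ROC step curve with segments dichotomized by whether
#' the realized FDR at each operating point is at or below the acceptable
#' level, and shades the region whose area is the FCAUC (the curve capped at
#' the TPR of the most liberal admissible cutoff). The shaded area is
#' printed in the plot annotation.
#'
#' @param object A `rocs_curve`.
#' @param fdr Acceptable FDR level in `[0, 1]`. Default 0.2.
#' @param ... Unused.
#' @return A ggplot object.
#' @examples
#' d <- labeled_scores(c(.9, .8, .7, .6, .5, .4), c(1, 1, 0, 0, 1, 0))
#' autoplot(rocs_curve(d), fdr = 0.2)
#' @exportS3Method ggplot2::autoplot
autoplot.rocs_curve <- function(object, fdr = 0.2, ...) {
  curve <- validate_rocs_curve(object)
  fc <- fcauc(curve, fdr = fdr)

  # step path through (0,0) and the operating points: vertical rise at each
  # point's FPR, horizontal run between points
  n <- nrow(curve)
  seg <- tibble::tibble(
    x = curve$fpr,
    y0 = c(0, curve$tpr[-n]),
    y1 = curve$tpr,
    ok = curve$fdr <= fdr
  )
  run <- tibble::tibble(
    x0 = curve$fpr[-n], x1 = curve$fpr[-1],
    y = curve$tpr[-n], ok = curve$fdr[-1] <= fdr
  )

  # FCAUC region: per-step rectangles under the capped curve
  ok_idx <- which(curve$fdr <= fdr)
  rects <- NULL
  if (length(ok_idx) > 0) {
    t_star <- curve$tpr[max(ok_idx)]
    y0 <- c(0, curve$tpr[-n])
    y1 <- pmin(curve$tpr, t_star)
    keep <- y1 > y0
    rects <- tibble::tibble(
      xmin = curve$fpr[keep], xmax = 1,
      ymin = pmin(y0, t_star)[keep], ymax = y1[keep]
    )
  }

  p <- ggplot2::ggplot()
  if (!is.null(rects) && nrow(rects) > 0) {
    p <- p + ggplot2::geom_rect(
      data = rects,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                   ymin = .data$ymin, ymax = .data$ymax),
      fill = "steelblue", alpha = 0.25)
  }
  p +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, xend = .data$x, y = .data$y0, yend = .data$y1,
                   colour = .data$ok), linewidth = 0.8) +
    ggplot2::geom_segment(
      data = run,
      ggplot2::aes(x = .data$x0, xend = .data$x1, y = .data$y, yend = .data$y,
                   colour = .data$ok), linewidth = 0.8) +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "firebrick", `FALSE` = "grey40"),
      labels = c(`TRUE` = paste0("FDR ≤ ", fdr),
                 `FALSE` = paste0("FDR > ", fdr)),
      name = NULL) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      subtitle = sprintf("FCAUC (shaded) = %.4g at FDR level %.3g", fc, fdr)) +
    ggplot2::theme_minimal()
}

#' Write the FDR-coloured ROC plot to an image file
#'
#' @inheritParams autoplot.rocs_curve
#' @param curve A `rocs_curve`.
#' @param path Output image path (`.png`, `.svg`, `.pdf`, ...).
#' @param width,height,dpi Device settings passed to [ggplot2::ggsave()].
#' @return `path`, invisibly.
#' @export
plot_roc_fdr <- function(curve, path, fdr = 0.2, width = 5, height = 4.5,
                         dpi = 150) {
  p <- autoplot.rocs_curve(curve, fdr = fdr)
  ggplot2::ggsave(path, plot = p, width = width, height = height, dpi = dpi)
  invisible(path)
}

#' Static 3D rendering of the ROC surface
#'
#' Renders the ruled surface that spans, at each TPR level, from the
#' operating-point curve out to `FPR = 1` at height TDR, above its floor
#' projection (the area under the ordinary ROC curve). The volume enclosed
#' is the VUS. Perfect separation gives a unit slab of height 1; severely
#' overlapping classes at large class ratio give a near-flat surface at low
#' TDR.
#'
#' @param curve A `rocs_curve`.
#' @param path Optional output PNG path; when `NULL` the surface is drawn on
#'   the current graphics device.
#' @param n_grid Resolution of the FPR/TPR evaluation grid. Default 80.
#' @param theta,phi Viewing angles passed to [graphics::persp()].
#' @return `path` (or `NULL`), invisibly.
#' @export
plot_rocs_surface <- function(curve, path = NULL, n_grid = 80, theta = -35,
                              phi = 25) {
  curve <- validate_rocs_curve(curve)
  tt <- seq(0, 1, length.out = n_grid)
  xx <- seq(0, 1, length.out = n_grid)
  # step lookup: TPR level t belongs to the first operating point reaching it
  idx <- findInterval(tt, c(0, curve$tpr), left.open = TRUE,
                      rightmost.closed = TRUE)
  idx[idx < 1] <- 1L
  idx[idx > nrow(curve)] <- nrow(curve)
  z <- outer(xx, seq_along(tt), function(x, j) {
    ifelse(x >= curve$fpr[idx[j]], curve$tdr[idx[j]], 0)
  })
  if (!is.null(path)) {
    grDevices::png(path, width = 900, height = 750, res = 130)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  graphics::persp(xx, tt, z, theta = theta, phi = phi, expand = 0.7,
                  col = "lightsteelblue", border = NA, shade = 0.55,
                  ticktype = "detailed",
                  xlab = "FPR", ylab = "TPR", zlab = "TDR",
                  zlim = c(0, 1),
                  main = sprintf("ROC surface (VUS = %.4g)", vus(curve)))
  invisible(path)
}
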