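#' Plot a clustered image map
#'
#' Heatmap of the z-scored matrix in dendrogram leaf order; the color key
#' is in standard deviations away from each feature's mean. Row side
#' colors mark the condition class.
#'
#' @param x a [CIMResult].
#' @param palette diverging color palette function.
#' @return invisibly, the reordered z matrix.
#' @export
plotCIM <- function(x, palette = grDevices::hcl.colors) {
  stopifnot(is(x, "CIMResult"))
  z <- x@z[x@rowOrder, x@colOrder, drop = FALSE]
  lim <- max(abs(z))
  op <- graphics::par(mar = c(6, 2, 2, 6))
  on.exit(graphics::par(op))
  graphics::image(t(z)[, rev(seq_len(nrow(z))), drop = FALSE],
                  col = palette(64, "Blue-Red 2"), zlim = c(-lim, lim),
                  axes = FALSE,
                  main = sprintf("CIM (%s linkage, SD units)", x@linkage))
  graphics::axis(1, at = seq(0, 1, length.out = ncol(z)),
                 labels = colnames(z), las = 2, cex.axis = 0.7)
  graphics::axis(4, at = seq(0, 1, length.out = nrow(z)),
                 labels = rev(paste(rownames(z), x@classes[x@rowOrder])),
                 las = 2, cex.axis = 0.6)
  invisible(z)
}

#' Plot PLS-DA loading bars
#'
#' Horizontal bars of the component-1 loadings; bar length is the
#' importance of a feature for discriminating the two classes, bar
#' direction the class it marks.
#'
#' @param model a [PLSDAModel].
#' @return invisibly, the ranking data.frame.
#' @export
plotLoadings <- function(model) {
  rk <- rankDiscriminativeFeatures(model)
  rk <- rk[order(rk$loading), ]
  cols <- ifelse(rk$loading >= 0, "#C0504D", "#4F81BD")
  op <- graphics::par(mar = c(4, 8, 2, 2))
  on.exit(graphics::par(op))
  graphics::barplot(rk$loading, names.arg = rk$feature, horiz = TRUE,
                    las = 1, col = cols, border = NA,
                    xlab = "component-1 loading",
                    main = sprintf("Feature importance (%s vs %s)",
                                   model@classLabels[1L],
                                   model@classLabels[2L]))
  invisible(rk)
}

#' Plot a correlogram
#'
#' Circle matrix: filled circles for significant positive correlations,
#' open circles for significant negative ones, circle size proportional
#' to |r|; non-significant pairs are drawn as blank (light blue) boxes.
#'
#' @param x a [CorrelogramResult].
#' @return invisibly `NULL`.
#' @export
plotCorrelogram <- function(x) {
  stopifnot(is(x, "CorrelogramResult"))
  k <- length(x@variables)
  op <- graphics::par(mar = c(1, 8, 8, 1))
  on.exit(graphics::par(op))
  graphics::plot(NA, xlim = c(0.5, k + 0.5), ylim = c(0.5, k + 0.5),
                 axes = FALSE, xlab = "", ylab = "", asp = 1)
  graphics::axis(3, at = seq_len(k), labels = x@variables, las = 2,
                 cex.axis = 0.7, tick = FALSE)
  graphics::axis(2, at = rev(seq_len(k)), labels = x@variables, las = 1,
                 cex.axis = 0.7, tick = FALSE)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    r <- x@r[i, j]; p <- x@p[i, j]
    cx <- j; cy <- k + 1 - i
    if (!is.finite(r) || (i != j && (!is.finite(p) || p >= x@alpha))) {
      graphics::rect(cx - 0.45, cy - 0.45, cx + 0.45, cy + 0.45,
                     col = "#D6E4F0", border = "grey80")
    } else {
      graphics::symbols(cx, cy, circles = abs(r) * 0.45, inches = FALSE,
                        add = TRUE, bg = if (r >= 0) "black" else "white",
                        fg = "black")
    }
  }
  invisible(NULL)
}
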