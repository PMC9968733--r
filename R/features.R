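# multi-scale per-pixel feature stack

shiftEdge <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) + dr, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) + dc, 1L), nc)
  m[ri, ci, drop = FALSE]
}

gradMag <- function(g) {
  gx <- (shiftEdge(g, 1L, 0L) - shiftEdge(g, -1L, 0L)) / 2
  gy <- (shiftEdge(g, 0L, 1L) - shiftEdge(g, 0L, -1L)) / 2
  sqrt(gx^2 + gy^2)
}

laplace4 <- function(g) {
  shiftEdge(g, 1L, 0L) + shiftEdge(g, -1L, 0L) +
    shiftEdge(g, 0L, 1L) + shiftEdge(g, 0L, -1L) - 4 * g
}

#' Compute the per-pixel feature stack of a two-channel tile
#'
#' For each channel: the raw intensity, plus, at every Gaussian scale
#' sigma, the smoothed intensity, its gradient magnitude and its Laplacian.
#' The feature count is therefore `channels * (3 * |scales|) + channels`
#' (20 for two channels and three scales). This is the trainable-pixel-
#' classification feature set; the scales are configurable.
#'
#' @param image a [ChannelImage].
#' @param scales Gaussian sigmas in px (>= 1 scale).
#' @return numeric matrix, one row per pixel (column-major order), one
#'   named column per feature; the image dimensions are kept in
#'   `attr(, "imageDim")`.
#' @export
computeFeatureStack <- function(image, scales = c(1, 2, 4)) {
  stopifnot(is(image, "ChannelImage"))
  if (!length(scales)) stop("at least one scale is required")
  chans <- list(body = image@body, nucleus = image@nucleus)
  if (!length(chans$body)) stop("empty image")
  cols <- list()
  for (cn in names(chans)) {
    x <- chans[[cn]]
    cols[[paste0(cn, "_raw")]] <- as.vector(x)
    for (s in scales) {
      g <- EBImage::gblur(x, s)
      cols[[sprintf("%s_s%g_gauss", cn, s)]] <- as.vector(g)
      cols[[sprintf("%s_s%g_grad", cn, s)]] <- as.vector(gradMag(g))
      cols[[sprintf("%s_s%g_lap", cn, s)]] <- as.vector(laplace4(g))
    }
  }
  out <- do.call(cbind, cols)
  attr(out, "imageDim") <- dim(chans$body)
  attr(out, "scales") <- scales
  out
}
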