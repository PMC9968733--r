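# internal helpers

# Run code under a fixed RNG seed without disturbing the caller's stream.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Named sub-seeds derived from one master seed; kept well below 2^31.
subSeed <- function(seed, stream) {
  offs <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 7919 + offs) %% 2147483629)
}

# 4-connected component labeling (wraps EBImage::bwlabel, which is
# 4-connected; diagonal contacts start new components).
label4 <- function(fg) {
  stopifnot(is.matrix(fg))
  lab <- EBImage::bwlabel(matrix(as.numeric(fg), nrow(fg), ncol(fg)))
  matrix(as.integer(lab), nrow(fg), ncol(fg))
}

# Signed polygon area (shoelace).
polyArea <- function(x, y) {
  n <- length(x)
  if (n < 3L) return(0)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# Area of the convex hull over the corners of all mask pixels, in px^2.
# Equals the hull of the pixel-corner boundary polygon, so convex
# rasterized shapes yield solidity exactly 1.
convexAreaPx <- function(rows, cols) {
  cx <- c(rows - 0.5, rows - 0.5, rows + 0.5, rows + 0.5)
  cy <- c(cols - 0.5, cols + 0.5, cols - 0.5, cols + 0.5)
  h <- grDevices::chull(cx, cy)
  polyArea(cx[h], cy[h])
}

# Proffitt-Rosen weighted chain-code perimeter over an 8-connected
# boundary chain through boundary-pixel centers (px units).
chainPerimeter <- function(contour) {
  n <- nrow(contour)
  if (is.null(n) || n < 2L) return(3.792)  # lone pixel: unit-square fallback
  nxt <- rbind(contour[-1L, , drop = FALSE], contour[1L, , drop = FALSE])
  dx <- abs(nxt[, 1L] - contour[, 1L])
  dy <- abs(nxt[, 2L] - contour[, 2L])
  diag <- dx > 0 & dy > 0
  0.948 * sum(!diag) + 1.340 * sum(diag)
}

# clamp preserving dim attributes (pmin/pmax with a scalar first arg drop them)
clamp01 <- function(x, lo = 0, hi = 1) {
  x[x < lo] <- lo
  x[x > hi] <- hi
  x
}

# Relabel positive labels to consecutive 1..k preserving first-appearance order.
relabelConsecutive <- function(lab) {
  ids <- sort(unique(lab[lab > 0L]))
  if (!length(ids)) return(lab)
  map <- integer(max(ids))
  map[ids] <- seq_along(ids)
  out <- lab
  pos <- lab > 0L
  out[pos] <- map[lab[pos]]
  out
}

#' Canonical names of the seven-descriptor shape panel
#'
#' @return character vector: area, length, width, circularity,
#'   aspect_ratio, roundness, solidity.
#' @export
descriptorNames <- function()
  c("area", "length", "width", "circularity", "aspect_ratio",
    "roundness", "solidity")
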