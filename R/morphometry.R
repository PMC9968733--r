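# Seven-descriptor single-cell shape panel.
#
# area = pixel count x px^2; length/width = major/minor axis of the ellipse
# with equal second central moments (a 1/12 px^2 term accounts for pixel
# extent); perimeter = Proffitt-Rosen weighted chain code; circularity =
# 4*pi*area/perimeter^2 (clamped at 1); aspect ratio = major/minor;
# roundness = 4*area/(pi*major^2) (clamped at 1); solidity = area / area of
# the convex hull over the pixel corners (exactly 1 for convex rasterized
# shapes).

measureOne <- function(rows, cols, px) {
  n <- length(rows)
  area <- n * px^2
  mr <- mean(rows); mc <- mean(cols)
  mu20 <- mean(rows^2) - mr^2 + 1 / 12
  mu02 <- mean(cols^2) - mc^2 + 1 / 12
  mu11 <- mean(rows * cols) - mr * mc
  tr <- mu20 + mu02
  dd <- sqrt((mu20 - mu02)^2 + 4 * mu11^2)
  majorPx <- 4 * sqrt((tr + dd) / 2)
  minorPx <- 4 * sqrt(max((tr - dd) / 2, 1 / 12))
  # local mask, padded, for boundary chain
  r0 <- min(rows); c0 <- min(cols)
  m <- matrix(0, max(rows) - r0 + 3L, max(cols) - c0 + 3L)
  m[cbind(rows - r0 + 2L, cols - c0 + 2L)] <- 1
  oc <- EBImage::ocontour(m)
  perimPx <- chainPerimeter(oc[[1L]])
  convA <- convexAreaPx(rows, cols) * px^2
  perim <- perimPx * px
  data.frame(
    area = area,
    length = majorPx * px,
    width = minorPx * px,
    circularity = min(1, 4 * pi * area / perim^2),
    aspect_ratio = majorPx / minorPx,
    roundness = min(1, 4 * area / (pi * (majorPx * px)^2)),
    solidity = min(1, area / convA),
    perimeter = perim,
    convex_area = convA)
}

#' Measure the shape-descriptor panel of a single cell mask
#'
#' Computes the seven-descriptor panel (area, length, width, circularity,
#' aspect ratio, roundness, solidity, plus auxiliary perimeter and convex
#' area) from one binary mask, in physical units. The mask must be a single
#' 4-connected component.
#'
#' @param mask logical or 0/1 matrix.
#' @param pixelSize microns per pixel (> 0).
#' @return one-row data.frame of descriptors (um, um^2, dimensionless).
#' @examples
#' m <- matrix(0, 80, 50); m[11:70, 11:40] <- 1  # filled rectangle
#' measureRegion(m, 1)$solidity  # exactly 1
#' @export
measureRegion <- function(mask, pixelSize) {
  stopifnot(is.matrix(mask), pixelSize > 0)
  idx <- which(mask > 0)
  if (!length(idx)) stop("empty mask")
  comp <- label4(mask > 0)
  if (max(comp) > 1L) stop("mask must be a single 4-connected component")
  rc <- arrayInd(idx, dim(mask))
  measureOne(rc[, 1L], rc[, 2L], pixelSize)
}

#' Measure every instance in a label map
#'
#' One row per instance id (ids preserved), with a border flag marking
#' instances touching the image edge. Instances whose pixel sets are split
#' into several 4-connected pieces (possible in ground-truth rasters when a
#' later cell occludes the middle of an earlier one) are measured on their
#' largest piece, with a warning.
#'
#' @param labelmap integer matrix, 0 = background.
#' @param pixelSize microns per pixel.
#' @return data.frame: `cell`, the descriptor panel, `n_px`, `border`.
#' @export
measureLabelMap <- function(labelmap, pixelSize) {
  stopifnot(is.matrix(labelmap), pixelSize > 0)
  idx <- which(labelmap > 0L)
  empty <- data.frame(cell = integer(0), area = numeric(0),
                      length = numeric(0), width = numeric(0),
                      circularity = numeric(0), aspect_ratio = numeric(0),
                      roundness = numeric(0), solidity = numeric(0),
                      perimeter = numeric(0), convex_area = numeric(0),
                      n_px = integer(0), border = logical(0))
  if (!length(idx)) return(empty)
  dm <- dim(labelmap)
  rc <- arrayInd(idx, dm)
  ids <- labelmap[idx]
  sp <- split(seq_along(idx), ids)
  nSplit <- 0L
  rows <- vector("list", length(sp))
  for (k in seq_along(sp)) {
    sel <- sp[[k]]
    r <- rc[sel, 1L]; cc <- rc[sel, 2L]
    r0 <- min(r); c0 <- min(cc)
    loc <- matrix(0, max(r) - r0 + 1L, max(cc) - c0 + 1L)
    loc[cbind(r - r0 + 1L, cc - c0 + 1L)] <- 1
    comp <- label4(loc > 0)
    if (max(comp) > 1L) {
      nSplit <- nSplit + 1L
      keep <- which.max(tabulate(comp[comp > 0L]))
      kp <- comp[cbind(r - r0 + 1L, cc - c0 + 1L)] == keep
      r <- r[kp]; cc <- cc[kp]
    }
    out <- measureOne(r, cc, pixelSize)
    out$cell <- as.integer(names(sp)[k])
    out$n_px <- length(r)
    out$border <- any(r == 1L | r == dm[1L] | cc == 1L | cc == dm[2L])
    rows[[k]] <- out
  }
  if (nSplit > 0L)
    warning(sprintf("%d instance(s) split by occlusion; measured largest piece",
                    nSplit))
  out <- do.call(rbind, rows)
  out <- out[order(out$cell),
             c("cell", "area", "length", "width", "circularity",
               "aspect_ratio", "roundness", "solidity", "perimeter",
               "convex_area", "n_px", "border")]
  rownames(out) <- NULL
  out
}

#' Aggregate per-cell descriptors to sample level
#'
#' Arithmetic mean of each descriptor per sample, with the cell count
#' recorded, as used for the sample-level correlograms and the CIM (the
#' average cell morphology value of each individual experiment).
#'
#' @param cells data.frame of per-cell records carrying a `sample_id`
#'   column and the descriptor columns.
#' @param expected optional character vector of sample ids; samples with
#'   zero cells are omitted with a warning.
#' @return data.frame: `sample_id`, `n_cells`, mean descriptors.
#' @export
aggregateBySample <- function(cells, expected = NULL) {
  stopifnot("sample_id" %in% names(cells))
  vars <- intersect(c(descriptorNames(), "perimeter", "convex_area"),
                    names(cells))
  if (!nrow(cells)) {
    if (length(expected))
      warning("samples with zero cells omitted: ",
              paste(expected, collapse = ", "))
    return(data.frame(sample_id = character(0), n_cells = integer(0)))
  }
  ag <- aggregate(cells[vars], by = list(sample_id = cells$sample_id), mean)
  cnt <- aggregate(list(n_cells = cells[[vars[1L]]]),
                   by = list(sample_id = cells$sample_id), length)
  out <- merge(cnt, ag, by = "sample_id", sort = TRUE)
  if (length(expected)) {
    miss <- setdiff(expected, out$sample_id)
    if (length(miss))
      warning("samples with zero cells omitted: ",
              paste(miss, collapse = ", "))
  }
  out
}
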