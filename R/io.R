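#' Read and write two-channel tiles and label maps as TIFF
#'
#' Tiles are stored as two-page 16-bit grayscale TIFFs (page 1 body, page
#' 2 nucleus); label maps as single-page 16-bit TIFFs holding the integer
#' instance ids. Round-trips are lossless for 16-bit data. The physical
#' pixel size is carried in configuration, not TIFF tags, for determinism.
#'
#' @param image a [ChannelImage].
#' @param path TIFF file path.
#' @param pixelSize microns per pixel to attach on read.
#' @param tileId tile id to attach on read.
#' @return `writeChannelImage`/`writeLabelMap` return the path invisibly;
#'   `readChannelImage` returns a [ChannelImage]; `readLabelMap` an
#'   integer matrix.
#' @export
writeChannelImage <- function(image, path) {
  stopifnot(is(image, "ChannelImage"))
  q <- function(m) round(clamp01(m) * 65535) / 65535
  tiff::writeTIFF(list(q(image@body), q(image@nucleus)), path,
                  bits.per.sample = 16L)
  invisible(path)
}

#' @rdname writeChannelImage
#' @export
readChannelImage <- function(path, pixelSize, tileId = basename(path)) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != 2L)
    stop("expected a 2-channel (2-page) TIFF: body and nucleus; got ",
         length(pages), " page(s)")
  for (pg in pages)
    if (length(dim(pg)) != 2L)
      stop("expected single-sample grayscale channels, got a ",
           dim(pg)[3L], "-sample page")
  new("ChannelImage", body = pages[[1L]], nucleus = pages[[2L]],
      pixelSize = pixelSize, tileId = tileId)
}

#' @rdname writeChannelImage
#' @param labelmap integer matrix of instance ids (< 65536).
#' @export
writeLabelMap <- function(labelmap, path) {
  stopifnot(is.matrix(labelmap), max(labelmap) < 65536L)
  tiff::writeTIFF(labelmap / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname writeChannelImage
#' @export
readLabelMap <- function(path) {
  pg <- tiff::readTIFF(path)
  if (length(dim(pg)) != 2L) stop("label map must be single-channel")
  matrix(as.integer(round(pg * 65535)), nrow(pg), ncol(pg))
}

#' Serialize an effect preset to JSON or YAML
#'
#' @param preset an [EffectPreset].
#' @param path output path ending in `.json`, `.yml` or `.yaml`.
#' @return `writePreset` returns the path invisibly; `readPreset` an
#'   [EffectPreset].
#' @export
writePreset <- function(preset, path) {
  stopifnot(is(preset, "EffectPreset"))
  lst <- list(name = preset@name,
              morphEffects = as.list(preset@morphEffects),
              geneEffects = as.list(preset@geneEffects),
              geneControlMeans = as.list(preset@geneControlMeans),
              baseline = as.list(preset@baseline),
              nPerGroup = preset@nPerGroup,
              seedingDensity = preset@seedingDensity, dose = preset@dose,
              exprDonorCV = preset@exprDonorCV,
              exprResidCV = preset@exprResidCV,
              morphDonorCV = preset@morphDonorCV)
  if (grepl("\\.json$", path))
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  else yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname writePreset
#' @export
readPreset <- function(path) {
  lst <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
  else yaml::read_yaml(path)
  new("EffectPreset", name = lst$name,
      morphEffects = unlist(lst$morphEffects),
      geneEffects = unlist(lst$geneEffects),
      geneControlMeans = unlist(lst$geneControlMeans),
      baseline = unlist(lst$baseline),
      nPerGroup = as.integer(lst$nPerGroup),
      seedingDensity = lst$seedingDensity, dose = lst$dose,
      exprDonorCV = lst$exprDonorCV, exprResidCV = lst$exprResidCV,
      morphDonorCV = lst$morphDonorCV)
}
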