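#' Physical pixel size accessor
#' @param x an object carrying a pixel size.
#' @return numeric(1), microns per pixel.
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @describeIn pixelSize pixel size of a tile.
#' @export
setMethod("pixelSize", "ChannelImage", function(x) x@pixelSize)

#' @describeIn pixelSize pixel size of a ground-truth scene.
#' @export
setMethod("pixelSize", "GroundTruthScene", function(x) x@pixelSize)

#' Channel accessor
#' @param x a [ChannelImage].
#' @param which `"body"` or `"nucleus"`.
#' @return numeric matrix of intensities.
#' @export
setGeneric("getChannel", function(x, which = c("body", "nucleus"))
  standardGeneric("getChannel"))

#' @describeIn getChannel extract one channel matrix.
#' @export
setMethod("getChannel", "ChannelImage", function(x, which = c("body", "nucleus")) {
  which <- match.arg(which)
  if (which == "body") x@body else x@nucleus
})

#' Ground-truth accessors
#' @param x a [GroundTruthScene].
#' @return `truthLabels`: integer label matrix; `truthClassMap`: integer
#'   class matrix; `truthPanel`: per-cell descriptor data.frame.
#' @export
setGeneric("truthLabels", function(x) standardGeneric("truthLabels"))
#' @rdname truthLabels
#' @export
setMethod("truthLabels", "GroundTruthScene", function(x) x@labels)
#' @rdname truthLabels
#' @export
setGeneric("truthClassMap", function(x) standardGeneric("truthClassMap"))
#' @rdname truthLabels
#' @export
setMethod("truthClassMap", "GroundTruthScene", function(x) x@classMap)
#' @rdname truthLabels
#' @export
setGeneric("truthPanel", function(x) standardGeneric("truthPanel"))
#' @rdname truthLabels
#' @export
setMethod("truthPanel", "GroundTruthScene", function(x) x@panel)

#' Preset accessors
#' @param x an [EffectPreset].
#' @return `presetName`: character(1); `morphologyEffects`, `geneEffects`:
#'   named numeric vectors of multiplicative effects.
#' @export
setGeneric("presetName", function(x) standardGeneric("presetName"))
#' @rdname presetName
#' @export
setMethod("presetName", "EffectPreset", function(x) x@name)
#' @rdname presetName
#' @export
setGeneric("morphologyEffects", function(x) standardGeneric("morphologyEffects"))
#' @rdname presetName
#' @export
setMethod("morphologyEffects", "EffectPreset", function(x) x@morphEffects)
#' @rdname presetName
#' @export
setGeneric("geneEffects", function(x) standardGeneric("geneEffects"))
#' @rdname presetName
#' @export
setMethod("geneEffects", "EffectPreset", function(x) x@geneEffects)

#' PLS-DA accessors
#' @param x a [PLSDAModel].
#' @return `plsWeights`, `plsLoadings`: p x ncomp matrices; `plsScores`:
#'   n x ncomp matrix.
#' @export
setGeneric("plsWeights", function(x) standardGeneric("plsWeights"))
#' @rdname plsWeights
#' @export
setMethod("plsWeights", "PLSDAModel", function(x) x@weights)
#' @rdname plsWeights
#' @export
setGeneric("plsLoadings", function(x) standardGeneric("plsLoadings"))
#' @rdname plsWeights
#' @export
setMethod("plsLoadings", "PLSDAModel", function(x) x@loadings)
#' @rdname plsWeights
#' @export
setGeneric("plsScores", function(x) standardGeneric("plsScores"))
#' @rdname plsWeights
#' @export
setMethod("plsScores", "PLSDAModel", function(x) x@scores)

setMethod("show", "ChannelImage", function(object) {
  d <- dim(object@body)
  cat(sprintf("ChannelImage '%s': %d x %d px, 2 channels, %.3g um/px\n",
              object@tileId, d[1], d[2], object@pixelSize))
})

setMethod("show", "GroundTruthScene", function(object) {
  cat(sprintf("GroundTruthScene: %d cells (%d border), %d x %d px, %.3g um/px\n",
              nrow(object@panel), sum(object@panel$border),
              nrow(object@labels), ncol(object@labels), object@pixelSize))
})

setMethod("show", "EffectPreset", function(object) {
  cat(sprintf("EffectPreset '%s' (dose %s ng/ml, %d per group, %.0f cells/cm^2)\n",
              object@name, object@dose, object@nPerGroup, object@seedingDensity))
  cat("  morphology effects: ",
      paste(sprintf("%s=%.3g", names(object@morphEffects), object@morphEffects),
            collapse = ", "), "\n", sep = "")
  if (length(object@geneEffects))
    cat("  gene fold changes:  ",
        paste(sprintf("%s=%.3g", names(object@geneEffects), object@geneEffects),
              collapse = ", "), "\n", sep = "")
})

setMethod("show", "TestResult", function(object) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (%s at alpha = %g)\n",
              object@test, object@statistic, object@p,
              if (object@significant) "significant" else "not significant",
              object@alpha))
})

setMethod("show", "CorrelogramResult", function(object) {
  cat(sprintf("CorrelogramResult: %d variables, alpha = %g\n",
              length(object@variables), object@alpha))
  cat("  methods used:", paste(unique(object@method[upper.tri(object@method)]),
                               collapse = ", "), "\n")
})

setMethod("show", "CIMResult", function(object) {
  cat(sprintf("CIMResult: %d samples x %d features, %s linkage\n",
              nrow(object@z), ncol(object@z), object@linkage))
  print(object@crosstab)
})

setMethod("show", "PLSDAModel", function(object) {
  cat(sprintf("PLSDAModel: %d component(s), %d features, classes %s/%s\n",
              object@ncomp, length(object@featureNames),
              object@classLabels[1], object@classLabels[2]))
  cat(sprintf("  X variance explained: %s\n",
              paste(sprintf("%.1f%%", 100 * object@explainedVarX), collapse = " + ")))
})
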