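#' @import methods
#' @importFrom stats aggregate complete.cases cor.test cutree dist hclust
#'   kruskal.test median pnorm qnorm rlnorm rnorm rpois runif sd setNames
#'   t.test var wilcox.test as.dendrogram quantile
#' @importFrom utils head modifyList read.csv write.csv
NULL

#' Two-channel fluorescence tile
#'
#' Container for one microscopy tile: a cell-body (calcein-like) channel and
#' a nucleus (Hoechst-like) channel on the same pixel grid, plus the physical
#' pixel size. Intensities are stored as doubles in [0, 1]; 16-bit TIFF
#' values are rescaled on read.
#'
#' @slot body numeric matrix, cell-body channel.
#' @slot nucleus numeric matrix, nucleus channel, same dimensions as `body`.
#' @slot pixelSize numeric(1), microns per pixel edge (> 0).
#' @slot tileId character(1) identifier.
#' @export
setClass("ChannelImage",
  representation(body = "matrix", nucleus = "matrix",
                 pixelSize = "numeric", tileId = "character"),
  prototype(pixelSize = 1, tileId = "tile"))

setValidity("ChannelImage", function(object) {
  msg <- character()
  if (!all(dim(object@body) == dim(object@nucleus)))
    msg <- c(msg, "body and nucleus channels must have identical dimensions")
  if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
      object@pixelSize <= 0)
    msg <- c(msg, "pixelSize must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Ground-truth scene for a rendered tile
#'
#' Produced alongside every rendered [ChannelImage]. `labels` records
#' per-pixel cell ownership after occlusion (0 = background), `classMap` the
#' true pixel class (0 background, 1 cytosol, 2 nucleus), `shapes` the
#' generating shape specifications, and `panel` the per-cell descriptor
#' panel measured from the rasterized ground-truth masks themselves (same
#' code path as [measureLabelMap()], so downstream measurements can be
#' compared exactly).
#'
#' @slot shapes data.frame of shape specifications (one row per cell).
#' @slot labels integer matrix, instance labels.
#' @slot classMap integer matrix, true pixel classes.
#' @slot panel data.frame, per-cell true descriptor panel with border flags.
#' @slot pixelSize numeric(1), microns per pixel.
#' @export
setClass("GroundTruthScene",
  representation(shapes = "data.frame", labels = "matrix",
                 classMap = "matrix", panel = "data.frame",
                 pixelSize = "numeric"))

setValidity("GroundTruthScene", function(object) {
  msg <- character()
  lab <- object@labels
  ids <- sort(unique(as.integer(lab[lab > 0])))
  if (length(ids) && !identical(ids, seq_along(ids)))
    msg <- c(msg, "instance labels must be consecutive positive integers")
  if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be positive")
  if (length(msg)) msg else TRUE
})

#' Experimental effect preset
#'
#' Bundles the study conditions for the synthetic generator: control-level
#' morphology parameters, per-descriptor multiplicative effects of treatment
#' on population means, per-gene expression fold changes, group sizes,
#' seeding density and the dose label. Shipped presets carry the printed
#' effect structure of the human-OA (0.1 ng/ml IL-1beta) and healthy bovine
#' (10 ng/ml IL-1beta) experiments; see [effectPreset()].
#'
#' @slot name character(1) preset name.
#' @slot morphEffects named numeric, multiplicative effects on the seven
#'   descriptor population means (treated vs control).
#' @slot geneEffects named numeric, fold changes treated vs control.
#' @slot geneControlMeans named numeric, control copies/uL per gene.
#' @slot baseline named numeric list of control morphology parameters
#'   (meanMajor um, meanAspect, cvMajor, cvAspect, protrusionRate,
#'   protrusionMeanLength um, protrusionWidth um, nucleusFrac).
#' @slot nPerGroup integer(1), samples per arm.
#' @slot seedingDensity numeric(1), cells/cm^2.
#' @slot dose character(1), dose label (ng/ml).
#' @slot exprDonorCV numeric(1) donor-level lognormal CV for expression.
#' @slot exprResidCV numeric(1) residual lognormal CV for expression.
#' @slot morphDonorCV numeric(1) donor-level CV on morphology means.
#' @export
setClass("EffectPreset",
  representation(name = "character", morphEffects = "numeric",
                 geneEffects = "numeric", geneControlMeans = "numeric",
                 baseline = "numeric", nPerGroup = "integer",
                 seedingDensity = "numeric", dose = "character",
                 exprDonorCV = "numeric", exprResidCV = "numeric",
                 morphDonorCV = "numeric"))

setValidity("EffectPreset", function(object) {
  msg <- character()
  if (any(object@morphEffects <= 0)) msg <- c(msg, "morphology multipliers must be > 0")
  if (any(object@geneEffects < 0)) msg <- c(msg, "gene fold changes must be >= 0")
  if (any(object@geneControlMeans < 0)) msg <- c(msg, "control means must be >= 0")
  if (object@nPerGroup < 1L) msg <- c(msg, "nPerGroup must be >= 1")
  if (object@seedingDensity <= 0) msg <- c(msg, "seedingDensity must be > 0")
  if (length(msg)) msg else TRUE
})

#' Trained three-class pixel classifier
#'
#' Probabilistic classifier over the classes background / cytosol / nucleus,
#' trained from scribble annotations on a multi-scale feature stack. The
#' default family is a probability forest of randomized decision trees.
#'
#' @slot model fitted ranger probability forest.
#' @slot scales numeric, Gaussian scales (px) of the feature stack.
#' @slot featureNames character, feature column names.
#' @slot classes character, class labels in posterior column order.
#' @export
setClass("PixelClassifier",
  representation(model = "ANY", scales = "numeric",
                 featureNames = "character", classes = "character"))

#' Result of a univariate statistical comparison
#'
#' @slot test character(1), the test that was run.
#' @slot statistic numeric(1).
#' @slot p numeric(1), two-sided p-value.
#' @slot alpha numeric(1).
#' @slot significant logical(1), `p < alpha`.
#' @slot groupSummary data.frame of per-group n, mean, median.
#' @slot gate list recording the normality-gate decision.
#' @export
setClass("TestResult",
  representation(test = "character", statistic = "numeric", p = "numeric",
                 alpha = "numeric", significant = "logical",
                 groupSummary = "data.frame", gate = "list"))

setValidity("TestResult", function(object) {
  if (is.finite(object@p) && (object@p < 0 || object@p > 1))
    "p-value must lie in [0, 1]" else TRUE
})

#' Correlogram over mixed continuous/categorical variables
#'
#' Pairwise correlation matrix with per-pair method dispatch: Spearman rank
#' correlation whenever either variable is categorical/ordinal (treatment
#' class, donor, macroscopic grade), Pearson otherwise.
#'
#' @slot variables character, variable names.
#' @slot r numeric matrix of correlations.
#' @slot p numeric matrix of two-sided p-values.
#' @slot method character matrix ("pearson"/"spearman") per pair.
#' @slot alpha numeric(1).
#' @export
setClass("CorrelogramResult",
  representation(variables = "character", r = "matrix", p = "matrix",
                 method = "matrix", alpha = "numeric"))

setValidity("CorrelogramResult", function(object) {
  msg <- character()
  r <- object@r
  if (!isTRUE(all.equal(r, t(r), tolerance = 1e-12)))
    msg <- c(msg, "correlation matrix must be symmetric")
  dr <- diag(r)
  if (any(abs(dr[is.finite(dr)] - 1) > 1e-12))
    msg <- c(msg, "finite diagonal entries must equal 1")
  if (any(abs(r[is.finite(r)]) > 1 + 1e-12))
    msg <- c(msg, "correlations must lie in [-1, 1]")
  if (length(msg)) msg else TRUE
})

#' Clustered image map (CIM)
#'
#' Z-scored feature matrix with Euclidean-distance hierarchical clustering
#' of rows (samples) and columns (features); the color scale of a rendered
#' CIM is in standard-deviation units away from the feature mean.
#'
#' @slot z numeric matrix, column-wise z-scores.
#' @slot rowTree,colTree hclust trees.
#' @slot rowOrder,colOrder integer leaf orders.
#' @slot classes factor, per-row condition class labels.
#' @slot crosstab table, 2-cluster row split vs condition class.
#' @slot linkage character(1) linkage method.
#' @export
setClass("CIMResult",
  representation(z = "matrix", rowTree = "ANY", colTree = "ANY",
                 rowOrder = "integer", colOrder = "integer",
                 classes = "factor", crosstab = "table",
                 linkage = "character"))

setValidity("CIMResult", function(object) {
  z <- object@z
  mu <- colMeans(z)
  s <- apply(z, 2L, sd)
  if (any(abs(mu) > 1e-9) || any(abs(s - 1) > 1e-9))
    "z matrix columns must have mean 0 and SD 1 (within 1e-9)" else TRUE
})

#' Fitted PLS-DA model (NIPALS)
#'
#' Partial least squares discriminant analysis against a 0/1 dummy-coded
#' class vector, extracted component-by-component with NIPALS on centered
#' data. Weight vectors have unit Euclidean norm and score vectors are
#' mutually orthogonal; per-feature importance is read from the
#' component-1 X-loading, signed toward the class it marks.
#'
#' @slot ncomp integer(1).
#' @slot weights p x ncomp matrix of unit-norm weight vectors.
#' @slot loadings p x ncomp matrix of X-loadings.
#' @slot scores n x ncomp matrix of X-scores.
#' @slot yLoadings numeric, per-component y-loadings.
#' @slot y numeric, the 0/1 class vector.
#' @slot classLabels character(2), labels for classes coded 0 and 1.
#' @slot featureNames character.
#' @slot explainedVarX numeric, fraction of X variance per component.
#' @export
setClass("PLSDAModel",
  representation(ncomp = "integer", weights = "matrix", loadings = "matrix",
                 scores = "matrix", yLoadings = "numeric", y = "numeric",
                 classLabels = "character", featureNames = "character",
                 explainedVarX = "numeric"))

setValidity("PLSDAModel", function(object) {
  msg <- character()
  wn <- sqrt(colSums(object@weights^2))
  if (any(abs(wn - 1) > 1e-8))
    msg <- c(msg, "weight vectors must have unit Euclidean norm")
  if (object@ncomp >= 2L) {
    g <- crossprod(object@scores)
    off <- g[upper.tri(g)] / sqrt(diag(g)[row(g)[upper.tri(g)]] *
                                  diag(g)[col(g)[upper.tri(g)]])
    if (any(abs(off) > 1e-8))
      msg <- c(msg, "score vectors must be orthogonal (within 1e-8)")
  }
  if (length(msg)) msg else TRUE
})
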