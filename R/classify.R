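segClasses <- function() c("background", "cytosol", "nucleus")

#' Sample training scribbles from a ground-truth scene
#'
#' Draws labeled pixel coordinates per class from the true class map,
#' emulating the manual scribble annotation used to train the pixel
#' classifier. As annotators do, a share of the background and cytosol
#' scribbles is placed along the cell boundaries (within `bandPx` of the
#' class edge), which anchors the decision boundary on the blurred cell
#' rim instead of leaving it to extrapolation.
#'
#' @param truth a [GroundTruthScene].
#' @param nPerClass pixels per class.
#' @param seed integer seed.
#' @param boundaryFrac fraction of background/cytosol scribbles drawn
#'   from the boundary band.
#' @param bandPx boundary band half-width in px.
#' @return data.frame `row`, `col`, `class` (0 background, 1 cytosol,
#'   2 nucleus).
#' @export
scribblesFromTruth <- function(truth, nPerClass = 500L, seed = 1L,
                               boundaryFrac = 0.5, bandPx = 2L) {
  cm <- truth@classMap
  fg <- cm > 0L
  kern <- EBImage::makeBrush(2L * bandPx + 1L, "diamond")
  halo <- EBImage::dilate(fg, kern) & !fg          # background near cells
  rim <- fg & !EBImage::erode(fg, kern)            # cytosol near edge
  withSeed(seed, {
    pick <- function(pool, n) pool[sample.int(length(pool), min(n, length(pool)))]
    out <- lapply(0:2, function(cl) {
      idx <- which(cm == cl)
      if (!length(idx)) stop("class ", cl, " absent from ground truth")
      nb <- if (cl == 2L) 0L else as.integer(round(nPerClass * boundaryFrac))
      band <- if (cl == 0L) which(halo & cm == 0L) else
        if (cl == 1L) which(rim & cm == 1L) else integer(0)
      sel <- c(pick(band, nb), pick(idx, nPerClass - min(nb, length(band))))
      rc <- arrayInd(sel, dim(cm))
      data.frame(row = rc[, 1L], col = rc[, 2L], class = cl)
    })
    scr <- do.call(rbind, out)
    scr[!duplicated(scr[c("row", "col")]), ]
  })
}

#' Train the three-class pixel classifier
#'
#' Fits a probability forest of randomized decision trees on the feature
#' rows at the scribble coordinates. The contract is a probabilistic
#' three-class classifier whose per-pixel posteriors sum to 1; training is
#' deterministic given the seed.
#'
#' @param features feature matrix from [computeFeatureStack()].
#' @param scribbles data.frame `row`, `col`, `class` with all three
#'   classes present; classes must be disjoint pixel sets.
#' @param seed integer seed.
#' @param numTrees trees in the forest.
#' @param minPerClass minimum labeled pixels required per class.
#' @return a [PixelClassifier].
#' @export
fitPixelClassifier <- function(features, scribbles, seed = 1L,
                               numTrees = 50L, minPerClass = 50L) {
  stopifnot(is.matrix(features), all(c("row", "col", "class") %in%
                                       names(scribbles)))
  dm <- attr(features, "imageDim")
  cnt <- table(factor(scribbles$class, levels = 0:2))
  if (any(cnt == 0L)) stop("missing class in scribbles: ",
                           paste(segClasses()[cnt == 0L], collapse = ", "))
  if (any(cnt < minPerClass))
    stop("each class needs at least ", minPerClass, " labeled pixels")
  key <- paste(scribbles$row, scribbles$col)
  if (any(tapply(scribbles$class, key, function(z) length(unique(z))) > 1L))
    stop("scribble classes must be disjoint pixel sets")
  lin <- (scribbles$col - 1L) * dm[1L] + scribbles$row
  x <- features[lin, , drop = FALSE]
  y <- factor(segClasses()[scribbles$class + 1L], levels = segClasses())
  fit <- ranger::ranger(x = x, y = y, num.trees = numTrees,
                        probability = TRUE, seed = as.integer(seed),
                        num.threads = 1L, min.node.size = 25L,
                        respect.unordered.factors = FALSE)
  new("PixelClassifier", model = fit, scales = attr(features, "scales"),
      featureNames = colnames(features), classes = segClasses())
}

#' Predict the per-pixel class map of a tile
#'
#' Computes the feature stack with the classifier's configuration, obtains
#' class posteriors, and assigns each pixel its argmax class with ties
#' broken toward background. Returns the class map (0 background,
#' 1 cytosol, 2 nucleus), optionally with the posterior array.
#'
#' @param classifier a [PixelClassifier].
#' @param image a [ChannelImage].
#' @param returnPosterior also return the posterior matrix.
#' @return integer class-map matrix, or (if `returnPosterior`) a list
#'   `classmap`, `posterior` (pixels x classes).
#' @export
predictClassMap <- function(classifier, image, returnPosterior = FALSE) {
  stopifnot(is(classifier, "PixelClassifier"), is(image, "ChannelImage"))
  features <- computeFeatureStack(image, classifier@scales)
  if (!identical(colnames(features), classifier@featureNames))
    stop("feature-dimension mismatch between classifier and image")
  pr <- predict(classifier@model, data = as.data.frame(features),
                num.threads = 1L)$predictions
  pr <- pr[, classifier@classes, drop = FALSE]  # background first
  cls <- max.col(pr, ties.method = "first") - 1L
  dm <- attr(features, "imageDim")
  cm <- matrix(as.integer(cls), dm[1L], dm[2L])
  if (returnPosterior) list(classmap = cm, posterior = pr) else cm
}
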