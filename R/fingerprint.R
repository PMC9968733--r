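#' Column-wise scaling and centering
#'
#' Z-scores each feature column (mean 0, SD 1, denominator n - 1);
#' constant columns are dropped with a warning. The centering/scaling
#' parameters are retained as attributes for inverse mapping.
#'
#' @param x numeric matrix (samples x features).
#' @return z-scored matrix with `center` and `scale` attributes.
#' @export
scaleCenter <- function(x) {
  x <- as.matrix(x)
  s <- apply(x, 2L, sd)
  if (all(s == 0)) stop("all columns are constant")
  if (any(s == 0)) {
    warning("dropping constant column(s): ",
            paste(colnames(x)[s == 0], collapse = ", "))
    x <- x[, s > 0, drop = FALSE]
  }
  z <- scale(x)
  out <- z[, , drop = FALSE]
  attr(out, "center") <- attr(z, "scaled:center")
  attr(out, "scale") <- attr(z, "scaled:scale")
  out
}

#' Clustered image map
#'
#' Hierarchical agglomerative clustering of samples (rows) and features
#' (columns) on Euclidean distances of the z-scored feature matrix;
#' complete linkage by default. The color scale of the map is in
#' standard-deviation units away from each feature's mean. A 2-cluster
#' row split is cross-tabulated against the condition classes.
#'
#' @param x numeric matrix, samples x features (raw scale; z-scored
#'   internally).
#' @param classes factor/vector of per-row condition labels.
#' @param linkage `"complete"` (default), `"average"` or `"ward.D2"`.
#' @return a [CIMResult].
#' @export
cim <- function(x, classes, linkage = c("complete", "average", "ward.D2")) {
  linkage <- match.arg(linkage)
  x <- as.matrix(x)
  if (nrow(x) < 3L) stop("need at least 3 rows")
  z <- scaleCenter(x)
  rowTree <- hclust(dist(z), method = linkage)
  colTree <- hclust(dist(t(z)), method = linkage)
  cl <- factor(classes)
  ct <- table(cluster = cutree(rowTree, k = 2L), class = cl)
  new("CIMResult", z = matrix(as.numeric(z), nrow(z), ncol(z),
                              dimnames = dimnames(z)),
      rowTree = rowTree, colTree = colTree,
      rowOrder = as.integer(rowTree$order),
      colOrder = as.integer(colTree$order),
      classes = cl, crosstab = ct, linkage = linkage)
}

#' Fit a PLS-DA model by NIPALS
#'
#' Partial least squares discriminant analysis of a feature matrix against
#' a 0/1 dummy-coded class vector. Components are extracted iteratively on
#' centered data: at each step the weight vector is proportional to
#' `t(X) %*% y_c` (unit norm), scores are `t = X w`, X-loadings
#' `p = t(X) t / (t' t)`, the y-loading `q = y' t / (t' t)`, and both X
#' and y are deflated before the next component. With a univariate
#' response the inner NIPALS loop converges in one pass, so the
#' single-component weight equals the normalized covariance of each
#' feature with the class, exactly. Initialization is deterministic (the
#' centered response); no randomness is involved.
#'
#' @param x numeric matrix, samples x features; supply z-scored data (see
#'   [scaleCenter()]) to put features on a common footing.
#' @param y class vector coded 0 (control) / 1 (treated), or a two-level
#'   factor (first level coded 0).
#' @param ncomp number of components (default 2; must not exceed the rank
#'   of `x`).
#' @param tol convergence tolerance of the inner loop.
#' @param maxIter maximum inner iterations.
#' @return a [PLSDAModel].
#' @export
plsdaFit <- function(x, y, ncomp = 2L, tol = 1e-10, maxIter = 500L) {
  x <- as.matrix(x)
  if (is.factor(y) || is.character(y)) {
    f <- factor(y)
    if (nlevels(f) != 2L) stop("y must have exactly two classes")
    labels <- levels(f)
    y <- as.numeric(f) - 1
  } else {
    if (!all(y %in% c(0, 1))) stop("y must be coded 0/1")
    labels <- c("0", "1")
  }
  if (length(unique(y)) < 2L) stop("degenerate y: single class")
  n <- nrow(x); pdim <- ncol(x)
  ncomp <- as.integer(ncomp)
  if (ncomp < 1L || ncomp > min(n - 1L, pdim))
    stop("ncomp must be between 1 and min(n - 1, p)")
  xc <- sweep(x, 2L, colMeans(x))
  yc <- y - mean(y)
  totVar <- sum(xc^2)
  W <- P <- matrix(0, pdim, ncomp)
  Tm <- matrix(0, n, ncomp)
  q <- numeric(ncomp)
  evar <- numeric(ncomp)
  Xd <- xc; yd <- yc
  for (h in seq_len(ncomp)) {
    u <- yd
    w <- crossprod(Xd, u)
    w <- w / sqrt(sum(w^2))
    it <- 0L
    repeat {
      t <- Xd %*% w
      qh <- sum(yd * t) / sum(t^2)
      uNew <- yd * qh  # univariate y: u-update, converges immediately
      wNew <- crossprod(Xd, uNew)
      wNew <- wNew / sqrt(sum(wNew^2))
      it <- it + 1L
      if (sum((wNew - w)^2) < tol^2 || it >= maxIter) { w <- wNew; break }
      w <- wNew
    }
    t <- Xd %*% w
    p <- crossprod(Xd, t) / sum(t^2)
    qh <- sum(yd * t) / sum(t^2)
    Xd <- Xd - t %*% t(p)
    yd <- yd - t * qh
    W[, h] <- w; P[, h] <- p; Tm[, h] <- t; q[h] <- qh
    evar[h] <- sum((t %*% t(p))^2) / totVar
  }
  fn <- colnames(x)
  if (is.null(fn)) fn <- paste0("V", seq_len(pdim))
  dimnames(W) <- dimnames(P) <- list(fn, paste0("comp", seq_len(ncomp)))
  dimnames(Tm) <- list(rownames(x), paste0("comp", seq_len(ncomp)))
  new("PLSDAModel", ncomp = ncomp, weights = W, loadings = P, scores = Tm,
      yLoadings = q, y = as.numeric(y), classLabels = labels,
      featureNames = fn, explainedVarX = evar)
}

#' Rank features by discriminative importance
#'
#' Orders features by the absolute value of their component-1 X-loading
#' and assigns each to the class its loading sign points toward under the
#' 0/1 coding (positive loadings mark the treated class, negative the
#' control class); the loading-bar-plot reading of feature importance.
#' Flipping the class labels flips every assignment but leaves the
#' ranking unchanged.
#'
#' @param model a fitted [PLSDAModel].
#' @return data.frame sorted by decreasing `|loading|`: `feature`,
#'   `loading`, `importance`, `class`.
#' @export
rankDiscriminativeFeatures <- function(model) {
  stopifnot(is(model, "PLSDAModel"))
  l1 <- model@loadings[, 1L]
  # component-1 y-loading is positive by construction (w ~ X'y), so a
  # positive X-loading marks the class coded 1
  out <- data.frame(feature = model@featureNames, loading = unname(l1),
                    importance = abs(unname(l1)),
                    class = ifelse(l1 >= 0, model@classLabels[2L],
                                   model@classLabels[1L]))
  out <- out[order(-out$importance), ]
  rownames(out) <- NULL
  out
}
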