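#' Normality-gated two-group comparison
#'
#' If both groups pass a normality gate at level `alpha`, a Student's
#' t-test (pooled variance) is used; otherwise the Mann-Whitney rank-sum
#' test with a tie-corrected normal approximation. The gate is the
#' Lilliefors variant of the Kolmogorov-Smirnov test (mean and SD
#' estimated from the data), since the plain KS test with estimated
#' parameters is anti-conservative; groups too small for the gate (n < 4)
#' or with zero variance are routed to the rank test.
#'
#' @param x,y numeric vectors (each n >= 3).
#' @param alpha significance level (default 0.05).
#' @param gate `"lilliefors"` or `"none"` (forces the rank test).
#' @return a [TestResult]; the gate decision is recorded in `@gate`.
#' @examples
#' compareTwoGroups(rnorm(8), rnorm(8) + 3)
#' @export
compareTwoGroups <- function(x, y, alpha = 0.05,
                             gate = c("lilliefors", "none")) {
  gate <- match.arg(gate)
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 3L || length(y) < 3L) stop("each group needs n >= 3")
  normalP <- function(v) {
    if (length(v) < 4L || sd(v) == 0) return(0)  # cannot assess: fail gate
    nortest::lillie.test(v)$p.value
  }
  gx <- if (gate == "lilliefors") normalP(x) else 0
  gy <- if (gate == "lilliefors") normalP(y) else 0
  useT <- gx > alpha && gy > alpha
  if (sd(x) == 0 || sd(y) == 0) {
    warning("zero-variance group; t-test undefined, using the rank test")
    useT <- FALSE
  }
  if (useT) {
    ht <- t.test(x, y, var.equal = TRUE)
    testName <- "Student's t-test"
  } else {
    ht <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
    testName <- "Mann-Whitney rank-sum test"
  }
  gs <- data.frame(group = c("x", "y"), n = c(length(x), length(y)),
                   mean = c(mean(x), mean(y)),
                   median = c(median(x), median(y)))
  new("TestResult", test = testName,
      statistic = unname(ht$statistic), p = unname(ht$p.value),
      alpha = alpha, significant = ht$p.value < alpha, groupSummary = gs,
      gate = list(method = gate, pNormalX = gx, pNormalY = gy,
                  usedT = useT))
}

# Dunn's z statistics on mean ranks, tie-corrected, all pairs.
dunnPairs <- function(groups, alpha) {
  k <- length(groups)
  pooled <- unlist(groups, use.names = FALSE)
  N <- length(pooled)
  rk <- rank(pooled)
  gid <- rep(seq_len(k), lengths(groups))
  meanRank <- tapply(rk, gid, mean)
  n <- lengths(groups)
  ties <- table(pooled)
  tieTerm <- sum(ties^3 - ties) / (12 * (N - 1))
  s2 <- N * (N + 1) / 12 - tieTerm
  pairs <- utils::combn(k, 2L)
  z <- apply(pairs, 2L, function(ij) {
    i <- ij[1L]; j <- ij[2L]
    (meanRank[i] - meanRank[j]) / sqrt(s2 * (1 / n[i] + 1 / n[j]))
  })
  p <- 2 * pnorm(-abs(z))
  data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ],
             meanRank1 = meanRank[pairs[1L, ]],
             meanRank2 = meanRank[pairs[2L, ]],
             z = z, p = p, significant = p < alpha)
}

#' ANOVA on ranks with Dunn's post-hoc comparisons
#'
#' Kruskal-Wallis omnibus test (tie-corrected) over three or more groups
#' of possibly unequal size; if requested (always computed), Dunn's method
#' compares all group pairs via z statistics on mean ranks with the pooled
#' tie-corrected variance. Pairwise decisions are taken at `alpha` without
#' multiple-testing adjustment (a Holm option is available but off by
#' default, matching the p < 0.05 convention).
#'
#' @param groups list of >= 3 numeric vectors, all non-empty.
#' @param alpha significance level.
#' @param adjust `"none"` (default) or `"holm"` for the pairwise p-values.
#' @return list: `omnibus` ([TestResult]) and `pairwise` (data.frame of
#'   Dunn results).
#' @export
multiGroupRanks <- function(groups, alpha = 0.05,
                            adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  if (!is.list(groups) || length(groups) < 3L)
    stop("need a list of at least 3 groups")
  if (any(lengths(groups) == 0L)) stop("empty group")
  ht <- kruskal.test(groups)
  gs <- data.frame(group = seq_along(groups), n = lengths(groups),
                   mean = vapply(groups, mean, 0),
                   median = vapply(groups, median, 0))
  omni <- new("TestResult", test = "Kruskal-Wallis rank ANOVA",
              statistic = unname(ht$statistic), p = unname(ht$p.value),
              alpha = alpha, significant = ht$p.value < alpha,
              groupSummary = gs, gate = list())
  pw <- dunnPairs(groups, alpha)
  if (adjust == "holm") {
    pw$p <- stats::p.adjust(pw$p, "holm")
    pw$significant <- pw$p < alpha
  }
  list(omnibus = omni, pairwise = pw)
}

#' Per-donor fold changes of a gene
#'
#' Fold change vs control with each control set to 1: for every donor, the
#' treated copies/uL divided by the donor-matched control copies/uL; the
#' group summary is the mean +/- SEM of the per-donor folds. When control
#' expression is essentially absent (median control below
#' `rawThreshold` copies/uL), division is meaningless and the gene is
#' reported in raw copies/uL instead, flagged via `mode = "copies"`.
#'
#' @param table sample table with `sample_id`, `donor`, `class` and gene
#'   columns (e.g. from [generateExpressionTable()]).
#' @param gene gene column name.
#' @param rawThreshold copies/uL below which controls count as near-zero.
#' @return list: `mode` ("fold" or "copies"), `perSample` data.frame
#'   (controls report 1 in fold mode), `mean`, `sem`.
#' @export
foldChange <- function(table, gene, rawThreshold = 0.5) {
  stopifnot(all(c("donor", "class", gene) %in% names(table)))
  ctrl <- table[table$class == 0L, ]
  trt <- table[table$class == 1L, ]
  m <- match(trt$donor, ctrl$donor)
  if (anyNA(m)) stop("every treated sample needs a donor-matched control")
  if (median(ctrl[[gene]]) < rawThreshold) {
    per <- data.frame(sample_id = c(ctrl$sample_id, trt$sample_id),
                      donor = c(ctrl$donor, trt$donor),
                      class = c(ctrl$class, trt$class),
                      value = c(ctrl[[gene]], trt[[gene]]))
    v <- trt[[gene]]
    return(list(mode = "copies", gene = gene, perSample = per,
                mean = mean(v), sem = sd(v) / sqrt(length(v))))
  }
  folds <- trt[[gene]] / ctrl[[gene]][m]
  per <- data.frame(sample_id = c(ctrl$sample_id, trt$sample_id),
                    donor = c(ctrl$donor, trt$donor),
                    class = c(ctrl$class, trt$class),
                    value = c(rep(1, nrow(ctrl)), folds))
  list(mode = "fold", gene = gene, perSample = per,
       mean = mean(folds), sem = sd(folds) / sqrt(length(folds)))
}

#' Percent-change comparison matrix
#'
#' For each ordered condition pair (a, b) and each descriptor, the percent
#' change `100 * (mean_b - mean_a) / mean_a`, with significance of the
#' underlying per-cell distributions assessed by [compareTwoGroups()]; the
#' analog of the color-coded condition-comparison tables.
#'
#' @param conditions named list of per-cell descriptor data.frames (one
#'   per condition), all sharing the descriptor columns.
#' @param comparisons list of `c(a, b)` condition-name pairs.
#' @param alpha significance level.
#' @param descriptors descriptor columns to compare.
#' @return list of matrices (`percent`, `significant`, `p`), descriptors
#'   x comparisons.
#' @export
percentChangeMatrix <- function(conditions, comparisons, alpha = 0.05,
                                descriptors = descriptorNames()) {
  stopifnot(length(names(conditions)) == length(conditions))
  if (any(!vapply(conditions, nrow, 0L))) stop("empty condition")
  cmpNames <- vapply(comparisons, function(ab)
    paste(ab[2L], "vs", ab[1L]), "")
  pct <- sig <- pv <- matrix(NA_real_, length(descriptors),
                             length(comparisons),
                             dimnames = list(descriptors, cmpNames))
  for (j in seq_along(comparisons)) {
    a <- conditions[[comparisons[[j]][1L]]]
    b <- conditions[[comparisons[[j]][2L]]]
    for (d in descriptors) {
      ma <- mean(a[[d]])
      if (ma == 0) stop("mean of '", d, "' is zero in condition ",
                        comparisons[[j]][1L])
      pct[d, j] <- 100 * (mean(b[[d]]) - ma) / ma
      tr <- compareTwoGroups(a[[d]], b[[d]], alpha)
      pv[d, j] <- tr@p
      sig[d, j] <- as.numeric(tr@significant)
    }
  }
  list(percent = pct, significant = sig == 1, p = pv)
}

#' Class-coded correlogram over mixed variables
#'
#' Pairwise correlations with per-pair method dispatch: Spearman rank
#' order if one or more of the pair is categorical/ordinal, Pearson
#' product-moment when both are numerical. The treatment class is coded
#' 0/1; donor and macroscopic grade count as categorical/ordinal by
#' default. P-values are two-sided; pairs whose p exceeds `alpha` are
#' flagged (rendered blank by [plotCorrelogram()]). Constant variables
#' yield `NA` correlations.
#'
#' @param data data.frame of samples or cells.
#' @param variables columns to correlate (default: all numeric).
#' @param categorical variables treated as categorical/ordinal.
#' @param alpha significance level.
#' @return a [CorrelogramResult].
#' @export
correlogram <- function(data, variables = NULL,
                        categorical = c("class", "donor", "grade"),
                        alpha = 0.05) {
  if (is.null(variables))
    variables <- names(data)[vapply(data, is.numeric, TRUE)]
  if (nrow(data) < 4L) stop("need at least 4 rows")
  k <- length(variables)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(variables, variables))
  meth <- matrix(NA_character_, k, k, dimnames = list(variables, variables))
  for (i in seq_len(k)) {
    for (j in i:k) {
      vi <- data[[variables[i]]]; vj <- data[[variables[j]]]
      method <- if (variables[i] %in% categorical ||
                    variables[j] %in% categorical) "spearman" else "pearson"
      meth[i, j] <- meth[j, i] <- method
      if (i == j) {
        if (sd(vi, na.rm = TRUE) > 0) { r[i, j] <- 1; p[i, j] <- 0 }
        next
      }
      ok <- complete.cases(vi, vj)
      if (sd(vi[ok]) == 0 || sd(vj[ok]) == 0) next  # undefined: stays NA
      ct <- suppressWarnings(cor.test(vi[ok], vj[ok], method = method,
                                      exact = FALSE))
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  new("CorrelogramResult", variables = variables, r = r, p = p,
      method = meth, alpha = alpha)
}
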