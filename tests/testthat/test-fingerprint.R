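test_that("scaleCenter z-scores exactly and is idempotent", {
  withr::with_seed(2, x <- matrix(rnorm(60, 5, 3), 10, 6,
                                  dimnames = list(NULL, letters[1:6])))
  z <- scaleCenter(x)
  expect_true(all(abs(colMeans(z)) < 1e-12))
  expect_true(all(abs(apply(z, 2, sd) - 1) < 1e-12))
  expect_equal(unclass(scaleCenter(z)), unclass(z), tolerance = 1e-12,
               ignore_attr = TRUE)
  # two rows: entries are +/- 1/sqrt(2)
  z2 <- scaleCenter(matrix(c(1, 3, 10, 2), 2, 2))
  expect_equal(abs(as.numeric(z2)), rep(1 / sqrt(2), 4))
  xc <- cbind(x, konst = 7)
  expect_warning(zc <- scaleCenter(xc), "constant")
  expect_identical(colnames(zc), colnames(x))
  expect_error(scaleCenter(matrix(1, 4, 2)), "constant")
})

test_that("CIM recovers block structure and merges duplicates first", {
  withr::with_seed(3, {
    blockA <- matrix(rnorm(40, 0, 0.3), 8, 5)
    blockB <- matrix(rnorm(40, 4, 0.3), 8, 5)
  })
  x <- rbind(blockA, blockB)
  colnames(x) <- paste0("f", 1:5)
  res <- cim(x, classes = rep(c("a", "b"), each = 8))
  cl2 <- cutree(res@rowTree, k = 2)
  expect_identical(length(unique(cl2[1:8])), 1L)
  expect_identical(length(unique(cl2[9:16])), 1L)
  expect_false(cl2[1] == cl2[9])
  expect_true(all(diag(as.matrix(res@crosstab)) %in% c(0L, 8L)))
  # duplicated row merges at height 0
  xd <- rbind(x, x[1, ])
  resd <- cim(xd, classes = c(rep(c("a", "b"), each = 8), "a"))
  expect_equal(min(resd@rowTree$height), 0)
  first <- resd@rowTree$merge[which.min(resd@rowTree$height), ]
  expect_setequal(-first, c(1L, 17L))
  expect_error(cim(x[1:2, ], classes = c("a", "b")), "3 rows")
})

test_that("NIPALS single-component weight equals normalized X'y_c exactly", {
  withr::with_seed(5, {
    x <- matrix(rnorm(14 * 6), 14, 6, dimnames = list(NULL, paste0("f", 1:6)))
    y <- rep(c(0, 1), each = 7)
  })
  z <- scaleCenter(x)
  m <- plsdaFit(z, y, ncomp = 1)
  w <- crossprod(z, y - mean(y))
  w <- w / sqrt(sum(w^2))
  expect_equal(as.numeric(plsWeights(m)[, 1]), as.numeric(w),
               tolerance = 1e-10)
})

test_that("NIPALS respects orthogonality, variance decay and reconstruction", {
  withr::with_seed(6, {
    x <- matrix(rnorm(12 * 5), 12, 5)
    y <- rep(c(0, 1), 6)
  })
  z <- scaleCenter(x)
  m <- plsdaFit(z, y, ncomp = 4)
  g <- crossprod(plsScores(m))
  expect_true(all(abs(g[upper.tri(g)] /
                        sqrt(diag(g)[row(g)[upper.tri(g)]] *
                             diag(g)[col(g)[upper.tri(g)]])) < 1e-8))
  expect_true(all(abs(sqrt(colSums(plsWeights(m)^2)) - 1) < 1e-10))
  ev <- m@explainedVarX
  expect_true(all(diff(ev[-1]) < 1e-9))   # non-increasing after the first
  expect_lte(sum(ev), 1 + 1e-9)
  # full-rank reconstruction: ncomp = min(n-1, p) restores centered X
  mFull <- plsdaFit(z, y, ncomp = min(nrow(z) - 1L, ncol(z)))
  zc <- sweep(z, 2, colMeans(z))
  rec <- plsScores(mFull) %*% t(plsLoadings(mFull))
  expect_lt(max(abs(rec - zc)), 1e-6)
  expect_error(plsdaFit(z, rep(0, 12)), "single class")
  expect_error(plsdaFit(z, y, ncomp = 50), "ncomp")
})

test_that("loading signs assign features to the class they mark", {
  withr::with_seed(7, {
    n <- 30
    y <- rep(c(0, 1), each = n / 2)
    x <- cbind(sep = y + rnorm(n, 0, 0.2),       # separates classes
               noise = rnorm(n))                  # pure noise
  })
  m <- plsdaFit(scaleCenter(x), y, ncomp = 1)
  rk <- rankDiscriminativeFeatures(m)
  expect_identical(rk$feature[1], "sep")
  expect_identical(rk$class[rk$feature == "sep"], "1")
  # flipping labels flips assignments, not the ranking
  m2 <- plsdaFit(scaleCenter(x), 1 - y, ncomp = 1)
  rk2 <- rankDiscriminativeFeatures(m2)
  expect_identical(rk$feature, rk2$feature)
  expect_identical(rk$importance, rk2$importance)
  expect_true(all(rk$class != rk2$class))
  # a zero-covariance feature carries the smallest |loading| in expectation
  imps <- withr::with_seed(8, vapply(1:40, function(i) {
    xx <- cbind(sep = y + rnorm(n, 0, 0.3), noise = rnorm(n))
    rr <- rankDiscriminativeFeatures(plsdaFit(scaleCenter(xx), y, ncomp = 1))
    rr$importance[rr$feature == "noise"] < rr$importance[rr$feature == "sep"]
  }, TRUE))
  expect_gt(mean(imps), 0.95)
})

test_that("our NIPALS agrees with an independent PLS-DA implementation", {
  skip_if_not_installed("mixOmics")
  withr::with_seed(9, {
    x <- matrix(rnorm(16 * 8), 16, 8, dimnames = list(NULL, paste0("f", 1:8)))
    x[9:16, 1:3] <- x[9:16, 1:3] + 1.5
    y <- rep(c(0, 1), each = 8)
  })
  z <- scaleCenter(x)
  ours <- plsdaFit(z, y, ncomp = 2)
  ref <- mixOmics::plsda(z, factor(y), ncomp = 2, scale = FALSE)
  refW <- ref$loadings$X[, 1]
  ourW <- plsWeights(ours)[, 1]
  s <- sign(sum(refW * ourW))
  expect_gt(abs(cor(ourW, s * refW)), 0.999)
})

test_that("sample-level fingerprints are seed-stable for the key features", {
  # default preset, data-level experiment: expression tables plus
  # sample-mean geometric descriptors from the shape generator
  p <- effectPreset("human_oa")
  tops <- lapply(1:10, function(s) {
    tab <- generateExpressionTable(p, 8, seed = 100 + s)
    morph <- t(vapply(seq_len(nrow(tab)), function(i) {
      pop <- generateShapePopulation(
        p, 250, seed = 200 + 16 * s + i,
        arm = if (tab$class[i] == 1L) "treated" else "control")
      c(area = mean(pi / 4 * pop$major * pop$minor),
        length = mean(pop$major), width = mean(pop$minor),
        aspect_ratio = mean(pop$major / pop$minor),
        roundness = mean(pop$minor / pop$major))
    }, numeric(5)))
    fm <- cbind(morph, as.matrix(tab[names(geneEffects(p))]))
    m <- plsdaFit(scaleCenter(fm), tab$class, ncomp = 2)
    rk <- rankDiscriminativeFeatures(m)
    genes <- rk[rk$feature %in% names(geneEffects(p)), ]
    descs <- rk[!rk$feature %in% names(geneEffects(p)), ]
    list(topTreatedGenes = sort(genes$feature[genes$class == "1"][1:2]),
         top2ControlDesc = descs$feature[descs$class == "0"][1:2])
  })
  # the leading features are seed-stable: the top treated-gene pair as a
  # set, and roundness always among the leading control descriptors
  # (exact order of near-tied loadings is not stable at n = 16 samples)
  expect_identical(length(unique(lapply(tops, `[[`, "topTreatedGenes"))), 1L)
  expect_true(all(vapply(tops, function(t)
    "roundness" %in% t$top2ControlDesc, TRUE)))
  firsts <- vapply(tops, function(t) t$top2ControlDesc[1], "")
  expect_identical(names(which.max(table(firsts))), "roundness")
})
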