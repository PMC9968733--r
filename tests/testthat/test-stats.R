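test_that("rank-sum statistic matches exhaustive enumeration on a 4+4 toy", {
  x <- c(1.2, 3.4, 2.2, 5.0)
  y <- c(0.7, 1.9, 2.2, 0.1)
  res <- compareTwoGroups(x, y, gate = "none")
  oracle <- bruteU(x, y)
  expect_identical(res@statistic, oracle$u)
  expect_lt(abs(res@p - oracle$pExact), 0.06)  # normal approx vs exact
  # a second toy with heavier ties
  x2 <- c(1, 2, 2, 3); y2 <- c(2, 2, 4, 5)
  res2 <- compareTwoGroups(x2, y2, gate = "none")
  expect_identical(res2@statistic, bruteU(x2, y2)$u)
})

test_that("identical samples give a null rank test; shifted Gaussians reject", {
  x <- c(5, 6, 7, 8, 9, 10)
  res <- compareTwoGroups(x, x, gate = "none")
  expect_gt(res@p, 0.9)  # p = 1 up to continuity correction
  expect_false(res@significant)
  expect_equal(res@groupSummary$mean[1], res@groupSummary$mean[2])
  # 3-SD shift at n = 8: significant in >= 99% of runs
  rej <- withr::with_seed(1, vapply(1:400, function(i)
    compareTwoGroups(rnorm(8), rnorm(8) + 3)@significant, TRUE))
  expect_gte(mean(rej), 0.99)
})

test_that("the normality gate routes data and degenerate input sanely", {
  skewed <- withr::with_seed(3, c(rexp(30), 50, 70, 90))  # wildly non-normal
  res <- withr::with_seed(4, compareTwoGroups(rnorm(30), skewed))
  expect_match(res@test, "Mann-Whitney")
  expect_false(res@gate$usedT)
  resN <- withr::with_seed(5, compareTwoGroups(rnorm(40), rnorm(40, 1)))
  expect_match(resN@test, "t-test")
  expect_warning(compareTwoGroups(rep(2, 6), rep(3, 6)), "zero-variance")
  expect_error(compareTwoGroups(c(1, 2), c(1, 2, 3)), "n >= 3")
})

test_that("Kruskal-Wallis H matches the closed form on a clean 3x3 input", {
  g <- list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9))
  res <- multiGroupRanks(g)
  # H = 12/(N(N+1)) * sum n_i (Rbar_i - (N+1)/2)^2 = 7.2, no ties
  expect_equal(res$omnibus@statistic, 7.2)
  expect_true(res$omnibus@significant)
  ident <- multiGroupRanks(list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3)))
  expect_false(ident$omnibus@significant)
  expect_true(all(!ident$pairwise$significant))
  expect_error(multiGroupRanks(list(1:3, 1:3)), "3 groups")
  expect_error(multiGroupRanks(list(1:3, 1:3, numeric(0))), "empty")
})

test_that("Dunn z statistics match an independent mean-rank implementation", {
  g <- list(c(2.5, 3.1, 4.0, 2.2), c(5.5, 6.1, 5.0), c(1.0, 1.2, 0.8, 1.5, 2.5))
  res <- multiGroupRanks(g)
  for (r in seq_len(nrow(res$pairwise))) {
    z <- oracleDunnZ(g, res$pairwise$group1[r], res$pairwise$group2[r])
    expect_equal(res$pairwise$z[r], z, tolerance = 1e-12)
  }
  # unequal group sizes are supported by construction
  expect_identical(nrow(res$pairwise), 3L)
})

test_that("fold changes follow the each-control-set-to-1 convention", {
  tab <- data.frame(sample_id = sprintf("S%d", 1:8), donor = rep(1:4, 2),
                    class = rep(c(0L, 1L), each = 4),
                    g = c(2, 4, 3, 5, 164, 328, 246, 410))
  fc <- foldChange(tab, "g")
  expect_identical(fc$mode, "fold")
  expect_identical(unique(fc$perSample$value[fc$perSample$class == 0]), 1)
  expect_equal(fc$mean, 82)
  expect_equal(fc$sem, 0)
  # control vs itself -> fold 1 exactly
  tabSame <- transform(tab, g = rep(c(2, 4, 3, 5), 2))
  expect_equal(foldChange(tabSame, "g")$mean, 1)
  # near-zero controls switch to raw copies/uL mode
  tabZero <- transform(tab, g = c(0, 0, 0.1, 0, 7, 9, 6, 8))
  fz <- foldChange(tabZero, "g")
  expect_identical(fz$mode, "copies")
  expect_equal(fz$mean, 7.5)
  # scale invariance of the fold under common rescaling
  tab2 <- transform(tab, g = g * 1000)
  expect_equal(foldChange(tab2, "g")$mean, fc$mean)
})

test_that("percent-change matrices recover means and significance flags", {
  withr::with_seed(8, {
    a <- data.frame(area = rnorm(400, 100, 5), length = rnorm(400, 30, 2))
    b <- data.frame(area = rnorm(400, 110, 5), length = rnorm(400, 30, 2))
  })
  pcm <- percentChangeMatrix(list(ctrl = a, trt = b),
                             list(c("ctrl", "trt")),
                             descriptors = c("area", "length"))
  expect_lt(abs(pcm$percent["area", 1] - 10), 1.5)
  expect_true(pcm$significant["area", 1])
  expect_false(pcm$significant["length", 1])
  ident <- percentChangeMatrix(list(x = a, y = a), list(c("x", "y")),
                               descriptors = c("area", "length"))
  expect_equal(unname(ident$percent[, 1]), c(0, 0))
  expect_true(all(!ident$significant))
  # exact scale invariance under common rescaling
  pcm2 <- percentChangeMatrix(list(ctrl = a * 3, trt = b * 3),
                              list(c("ctrl", "trt")),
                              descriptors = c("area", "length"))
  expect_equal(pcm2$percent, pcm$percent)
  bad <- data.frame(area = c(-1, 1, 0), length = 1:3)
  expect_error(percentChangeMatrix(list(x = bad, y = a), list(c("x", "y")),
                                   descriptors = "area"), "zero")
})

test_that("Spearman on a 5-row toy matches brute-force rank-then-Pearson", {
  d <- data.frame(class = c(0, 0, 1, 1, 1),
                  v = c(2.2, 1.1, 5.5, 3.3, 4.4),
                  w = c(10, 12, 9, 14, 11))
  cg <- correlogram(d, variables = c("class", "v", "w"))
  oracle <- function(a, b) {
    ra <- rank(a); rb <- rank(b)
    sum((ra - mean(ra)) * (rb - mean(rb))) /
      sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
  }
  expect_equal(cg@r["class", "v"], oracle(d$class, d$v), tolerance = 1e-12)
  expect_equal(cg@r["class", "w"], oracle(d$class, d$w), tolerance = 1e-12)
  expect_identical(cg@method["class", "v"], "spearman")
  expect_identical(cg@method["v", "w"], "pearson")
  expect_identical(cg@r["v", "v"], 1)
})

test_that("correlograms are symmetric, class-coded and permutation-invariant", {
  withr::with_seed(11, {
    n <- 40
    d <- data.frame(class = rep(0:1, each = n / 2))
    d$area <- rnorm(n, 100 + 15 * d$class, 8)  # positive treatment shift
    d$round <- rnorm(n, 0.6 - 0.1 * d$class, 0.05)
    d$flat <- rep(3, n)
  })
  cg <- correlogram(d)
  expect_equal(cg@r, t(cg@r))
  expect_gt(cg@r["class", "area"], 0)
  expect_lt(cg@p["class", "area"], 0.05)
  expect_lt(cg@r["class", "round"], 0)
  expect_true(all(is.na(cg@r["flat", colnames(cg@r) != "flat"])))
  cgPerm <- correlogram(d[sample(nrow(d)), ])
  expect_equal(cg@r, cgPerm@r)
  expect_error(correlogram(d[1:3, ]), "4 rows")
})
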