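test_that("shape populations are seeded-deterministic and respect invariants", {
  p <- effectPreset("human_oa")
  a <- generateShapePopulation(p, 50, seed = 5)
  b <- generateShapePopulation(p, 50, seed = 5)
  expect_identical(a, b)
  c <- generateShapePopulation(p, 50, seed = 6)
  expect_false(identical(a$major, c$major))
  expect_true(all(a$major >= a$minor))
  expect_true(all(a$minor > 0))
  expect_true(all(a$nucleusDiameter < a$minor))
  expect_true(all(unlist(lapply(a$protrusions, function(pr) pr$length)) >= 0))
  expect_error(generateShapePopulation(p, 0, seed = 1), "nCells")
})

test_that("zero protrusion rate yields convex (solidity-1) cells", {
  p <- effectPreset("bovine_10ng")
  pop <- generateShapePopulation(p, 30, seed = 9, arm = "control",
                                 baselineOverride = c(protrusionRate = 0))
  expect_true(all(vapply(pop$protrusions, nrow, 0L) == 0L))
  sc <- renderScene(pop, c(900, 900), 1.5,
                    noise = renderNoise(blurSigma = 0, photonScale = 0,
                                        readSigma = 0, background = 0),
                    seed = 10)
  pan <- truthPanel(sc$truth)
  # convex generating shapes; the hull bridges the rasterization
  # staircase, so solidity of ~23 px cells sits a few percent below 1
  expect_true(all(pan$solidity > 0.90))
  expect_gt(mean(pan$solidity), 0.92)
})

test_that("bovine-control population mean major axis matches 35 um within 2%", {
  p <- effectPreset("bovine_10ng")
  pop <- generateShapePopulation(p, 5000, seed = 2, arm = "control")
  expect_lt(abs(mean(pop$major) - 35) / 35, 0.02)
})

test_that("rendered ground truth is self-consistent with its label raster", {
  p <- effectPreset("human_oa")
  pop <- generateShapePopulation(p, 40, seed = 21, arm = "control")
  sc <- renderScene(pop, c(1000, 1000), 2, seed = 22)
  lab <- truthLabels(sc$truth)
  pan <- truthPanel(sc$truth)
  ids <- sort(unique(lab[lab > 0]))
  expect_identical(ids, seq_along(ids))  # consecutive labels
  # true-panel areas equal pixel counts x pixel_size^2 of the raster
  pxCount <- tabulate(lab[lab > 0])
  expect_equal(pan$n_px, pxCount)
  expect_equal(pan$area, pxCount * 2^2)
  expect_equal(mean(pan$area), mean(pxCount) * 4)
  # panels equal measureLabelMap on the raster: same code path, exact
  expect_equal(pan[names(pan) != "tile"],
               measureLabelMap(lab, 2)[names(pan) != "tile"])
})

test_that("single disc renders one label; overlapping bodies keep two labels", {
  p <- effectPreset("null")
  one <- generateShapePopulation(p, 1, seed = 1, arm = "control",
                                 baselineOverride = c(protrusionRate = 0,
                                                      meanAspect = 1))
  one$cx <- 100; one$cy <- 100
  sc <- renderScene(one, c(200, 200), 1, seed = 2)
  expect_identical(max(truthLabels(sc$truth)), 1L)
  two <- generateShapePopulation(p, 2, seed = 3, arm = "control",
                                 baselineOverride = c(protrusionRate = 0,
                                                      meanAspect = 1,
                                                      meanMajor = 50,
                                                      cvMajor = 0.05))
  two$cx <- c(90, 120); two$cy <- c(100, 100)  # bodies overlap
  sc2 <- renderScene(two, c(220, 220), 1, seed = 4)
  expect_identical(max(truthLabels(sc2$truth)), 2L)
  expect_error(renderScene(two, c(4, 4), 1, seed = 1), "too small")
})

test_that("expression tables obey closed-form and preset fold structure", {
  p <- effectPreset("human_oa")
  expect_identical(generateExpressionTable(p, 8, seed = 3),
                   generateExpressionTable(p, 8, seed = 3))
  # zero noise: treated = control mean x fold exactly
  p0 <- p
  p0@exprDonorCV <- 0; p0@exprResidCV <- 0
  tab <- generateExpressionTable(p0, 4, seed = 1)
  expect_equal(unique(tab$IL6[tab$class == 0]), 2)
  expect_equal(unique(tab$IL6[tab$class == 1]), 164)
  expect_equal(foldChange(tab, "IL6")$mean, 82)
  # null preset: expected treated/control ratio 1 for every gene
  pn <- effectPreset("null")
  rrs <- vapply(1:60, function(s) {
    t2 <- generateExpressionTable(pn, 8, seed = 7000 + s)
    mean(t2$COL2A1[t2$class == 1]) / mean(t2$COL2A1[t2$class == 0])
  }, 0)
  expect_lt(abs(mean(rrs) - 1), 0.05)
  expect_error(generateExpressionTable(p, 1, seed = 1), "nPerGroup")
})

test_that("mean paired IL-6 fold change converges to the preset value", {
  p <- effectPreset("human_oa")
  folds <- vapply(1:60, function(s)
    foldChange(generateExpressionTable(p, 8, seed = s), "IL6")$mean, 0)
  # paired design cancels the donor term; residual noise inflates the
  # arithmetic mean ratio by exp(sigma_resid^2) ~ 2%
  expect_lt(abs(mean(folds) / 82 - 1), 0.10)
})

test_that("effect fidelity: controlled group-mean ratios within 2% over 50 seeds", {
  p <- effectPreset("human_oa")
  eff <- morphologyEffects(p)
  rats <- t(vapply(1:50, function(s) {
    a <- generateShapePopulation(p, 2000, seed = 2 * s, arm = "control")
    b <- generateShapePopulation(p, 2000, seed = 2 * s + 1, arm = "treated")
    c(area = mean(pi / 4 * b$major * b$minor) /
        mean(pi / 4 * a$major * a$minor),
      ar = mean(b$major / b$minor) / mean(a$major / a$minor),
      len = mean(b$major) / mean(a$major))
  }, c(area = 0, ar = 0, len = 0)))
  expect_lt(abs(mean(rats[, "area"]) / eff[["area"]] - 1), 0.02)
  expect_lt(abs(mean(rats[, "ar"]) / eff[["aspect_ratio"]] - 1), 0.02)
  expect_lt(abs(mean(rats[, "len"]) /
                  sqrt(eff[["area"]] * eff[["aspect_ratio"]]) - 1), 0.02)
})

test_that("buildExperiment emits a paired 2n-row sample table and scales with density", {
  p <- effectPreset("human_oa")
  ex <- buildExperiment(p, seed = 5, tilePx = c(96L, 96L))
  expect_identical(nrow(ex$table), 16L)
  expect_identical(sum(ex$table$class == 1L), 8L)
  expect_setequal(ex$table$donor[ex$table$class == 1],
                  ex$table$donor[ex$table$class == 0])
  expect_identical(ex$table$grade, donorGrades()$grade[ex$table$donor])
  ex2 <- buildExperiment(p, seed = 5, tilePx = c(96L, 96L))
  expect_identical(ex$table, ex2$table)
  # low vs high seeding density: cells per unit area ratio ~ 3000/9375
  lo <- buildExperiment(p, seed = 1, tilePx = c(512L, 512L), density = 3000,
                        nPerGroup = 2L)
  hi <- buildExperiment(p, seed = 1, tilePx = c(512L, 512L), density = 9375,
                        nPerGroup = 2L)
  expect_lt(abs(lo$cellsPerTile / hi$cellsPerTile - 3000 / 9375), 0.02)
})
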