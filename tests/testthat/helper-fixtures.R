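# shared fixtures, built once per test run and cached

.fixtures <- new.env(parent = emptyenv())

# A mid-size rendered control tile with trained classifier; used by the
# segmentation tests.
segFixture <- function() {
  if (is.null(.fixtures$seg)) {
    preset <- effectPreset("bovine_10ng")
    pop <- generateShapePopulation(preset, 120L, seed = 41L, arm = "control")
    scene <- renderScene(pop, c(768, 768), 2, seed = 42L)
    feats <- computeFeatureStack(scene$image)
    scr <- scribblesFromTruth(scene$truth, 800L, seed = 43L)
    clf <- fitPixelClassifier(feats, scr, seed = 44L)
    .fixtures$seg <- list(preset = preset, scene = scene, feats = feats,
                          scribbles = scr, clf = clf)
  }
  .fixtures$seg
}

# The default human-OA synthetic experiment run through the full pipeline;
# used by the fingerprint and acceptance tests.
pipelineFixture <- function() {
  if (is.null(.fixtures$pipe)) {
    cfg <- pipelineConfig("human_oa", seed = 7L)
    .fixtures$pipe <- suppressWarnings(suppressMessages(runPipeline(cfg)))
  }
  .fixtures$pipe
}

# rasterize a filled disc / ellipse, axis-aligned, centered
discMask <- function(r, pad = 4L) {
  n <- 2L * (r + pad) + 1L
  cx <- r + pad + 1L
  m <- matrix(0L, n, n)
  ij <- arrayInd(seq_len(n * n), c(n, n))
  m[(ij[, 1L] - cx)^2 + (ij[, 2L] - cx)^2 <= r^2] <- 1L
  m
}

ellipseMask <- function(a, b, pad = 4L) {
  n1 <- 2L * (a + pad) + 1L
  n2 <- 2L * (b + pad) + 1L
  c1 <- a + pad + 1L
  c2 <- b + pad + 1L
  m <- matrix(0L, n1, n2)
  ij <- arrayInd(seq_len(n1 * n2), c(n1, n2))
  m[((ij[, 1L] - c1) / a)^2 + ((ij[, 2L] - c2) / b)^2 <= 1] <- 1L
  m
}

# brute-force Mann-Whitney U and its exact permutation p-value
bruteU <- function(x, y) {
  u <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  pooled <- c(x, y)
  idx <- utils::combn(length(pooled), length(x))
  us <- apply(idx, 2L, function(ii) {
    xx <- pooled[ii]; yy <- pooled[-ii]
    sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
  })
  mu <- length(x) * length(y) / 2
  list(u = u, pExact = mean(abs(us - mu) >= abs(u - mu) - 1e-12))
}

# independent Dunn z: explicit mean-rank formula, written separately from
# the implementation (no shared code path)
oracleDunnZ <- function(groups, i, j) {
  pooled <- unlist(groups)
  N <- length(pooled)
  rk <- rank(pooled)
  starts <- cumsum(c(0L, lengths(groups)))
  ri <- mean(rk[(starts[i] + 1L):starts[i + 1L]])
  rj <- mean(rk[(starts[j] + 1L):starts[j + 1L]])
  tie <- table(pooled)
  sig2 <- (N * (N + 1) / 12) - sum(tie^3 - tie) / (12 * (N - 1))
  (ri - rj) / sqrt(sig2 * (1 / lengths(groups)[i] + 1 / lengths(groups)[j]))
}
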