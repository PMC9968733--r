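#' Morphology recovery experiment through the full image pipeline
#'
#' Renders a control and a treated cell population of a preset, trains the
#' pixel classifier on one control tile, segments every tile, measures the
#' descriptor panel of every interior cell, and reports the percent change
#' of each mean descriptor between the arms; the end-to-end check that the
#' imaging pipeline recovers the preset's population effects.
#'
#' The two arms share the population and rendering random substreams
#' (common random numbers): the treated arm re-uses the control arm's
#' underlying draws with the preset multipliers applied, so the estimated
#' contrast is not inflated by independent sampling noise and the whole
#' experiment is deterministic given `seed`.
#'
#' @param preset preset name or [EffectPreset].
#' @param nCellsPerGroup cells rendered per arm (across tiles).
#' @param seed integer master seed.
#' @param cellsPerTile cells per rendered tile.
#' @param tilePx tile side in px.
#' @param pxSize microns per pixel.
#' @param noise noise model, see [renderNoise()].
#' @param alpha significance level for the percent-change tests.
#' @return list: `cells` (per-arm per-cell data.frames), `percentChange`
#'   (from [percentChangeMatrix()]), `meanControl`, `meanTreated` (named
#'   mean descriptor vectors), `nCells` (per arm).
#' @export
morphologyRecovery <- function(preset, nCellsPerGroup = 1600L, seed = 1L,
                               cellsPerTile = 160L, tilePx = 512L,
                               pxSize = 2, noise = renderNoise(),
                               alpha = 0.05) {
  if (is.character(preset)) preset <- effectPreset(preset)
  stopifnot(is(preset, "EffectPreset"))
  nTiles <- as.integer(ceiling(nCellsPerGroup / cellsPerTile))
  fieldUm <- c(tilePx, tilePx) * pxSize

  trainPop <- generateShapePopulation(preset, cellsPerTile,
                                      subSeed(seed, "train-pop"),
                                      arm = "control")
  trainScene <- renderScene(trainPop, fieldUm, pxSize, noise,
                            seed = subSeed(seed, "train-render"))
  feats <- computeFeatureStack(trainScene$image)
  scr <- scribblesFromTruth(trainScene$truth, 1000L,
                            subSeed(seed, "scribbles"))
  clf <- fitPixelClassifier(feats, scr, subSeed(seed, "forest"))

  arms <- c("control", "treated")
  cells <- setNames(vector("list", 2L), arms)
  for (arm in arms) {
    got <- list()
    for (i in seq_len(nTiles)) {
      pop <- generateShapePopulation(preset, cellsPerTile,
                                     subSeed(seed, paste0("pop-", i)),
                                     arm = arm)
      sc <- renderScene(pop, fieldUm, pxSize, noise,
                        seed = subSeed(seed, paste0("render-", i)),
                        tileId = sprintf("%s-%d", arm, i))
      cmap <- predictClassMap(clf, sc$image)
      lab <- instancesFromClassMap(cmap, pxSize)
      pan <- measureLabelMap(lab, pxSize)
      if (nrow(pan)) {
        pan$tile <- i
        got[[length(got) + 1L]] <- pan
      }
    }
    cells[[arm]] <- do.call(rbind, got)
  }
  pcm <- percentChangeMatrix(cells, list(c("control", "treated")), alpha)
  list(cells = cells, percentChange = pcm,
       meanControl = colMeans(cells$control[descriptorNames()]),
       meanTreated = colMeans(cells$treated[descriptorNames()]),
       nCells = vapply(cells, nrow, 0L))
}
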