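#' Pipeline configuration
#'
#' Assembles and validates the configuration for [runPipeline()]. All
#' physical units are um / um^2 / copies-per-uL. Every random draw in the
#' pipeline flows from the single `seed` via named substreams; there is no
#' hidden global RNG state (the caller's RNG is left untouched).
#'
#' @param preset preset name (see [effectPreset()]), an [EffectPreset], or
#'   a path to a preset JSON/YAML file.
#' @param seed integer master seed.
#' @param nPerGroup samples per arm.
#' @param tilePx tile size in px.
#' @param pxSize microns per pixel.
#' @param noise noise model, see [renderNoise()].
#' @param scales feature-stack Gaussian scales (px).
#' @param minArea instance area floor (um^2).
#' @param borderPolicy `"exclude"` or `"keep"`.
#' @param alpha significance level.
#' @param ncomp PLS-DA components.
#' @param linkage CIM linkage method.
#' @param outDir optional output directory; stage outputs are written as
#'   they complete.
#' @return validated config list (class `"pipelineConfig"`).
#' @export
pipelineConfig <- function(preset = "human_oa", seed = 1L, nPerGroup = 8L,
                           tilePx = c(384L, 384L), pxSize = 2,
                           noise = renderNoise(), scales = c(1, 2, 4),
                           minArea = 50, borderPolicy = "exclude",
                           alpha = 0.05, ncomp = 2L, linkage = "complete",
                           outDir = NULL) {
  if (is.character(preset)) {
    preset <- if (file.exists(preset)) readPreset(preset) else
      effectPreset(preset)
  }
  stopifnot(is(preset, "EffectPreset"), pxSize > 0, alpha > 0, alpha < 1)
  cfg <- list(preset = preset, seed = as.integer(seed),
              nPerGroup = as.integer(nPerGroup),
              tilePx = as.integer(tilePx), pxSize = pxSize, noise = noise,
              scales = scales, minArea = minArea,
              borderPolicy = borderPolicy, alpha = alpha,
              ncomp = as.integer(ncomp), linkage = linkage, outDir = outDir)
  class(cfg) <- "pipelineConfig"
  cfg
}

stageTry <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full fingerprinting pipeline
#'
#' Executes simulate (synthetic experiment) -> segment (train pixel
#' classifier on the first control tile, predict all tiles, watershed
#' instances) -> measure (per-cell descriptor panel, sample aggregation)
#' -> stats (per-gene fold changes, per-descriptor two-group tests,
#' percent-change matrix, sample-level correlogram) -> fingerprint (CIM
#' and PLS-DA on mean morphology + gene expression). Re-running with the
#' same configuration reproduces all numeric outputs bit-for-bit; the
#' manifest records the seed, configuration and per-stage row counts
#' together with a deterministic signature of the sample table.
#'
#' @param config a [pipelineConfig()].
#' @return list: `table` (sample table with mean descriptors), `cells`
#'   (per-cell records), `stats` (fold changes, descriptor tests,
#'   percent-change matrix, correlogram), `cim`, `plsda`, `ranking`,
#'   `manifest`.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "pipelineConfig"))
  out <- if (!is.null(config$outDir)) {
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    config$outDir
  } else NULL

  exp <- stageTry("simulate",
    buildExperiment(config$preset, seed = config$seed,
                    nPerGroup = config$nPerGroup, tilePx = config$tilePx,
                    pxSize = config$pxSize, noise = config$noise))
  if (!is.null(out))
    write.csv(exp$table, file.path(out, "sample_table_raw.csv"),
              row.names = FALSE)

  seg <- stageTry("segment", {
    trainScene <- exp$scenes[[which(exp$table$class == 0L)[1L]]][[1L]]
    feats <- computeFeatureStack(trainScene$image, config$scales)
    scr <- scribblesFromTruth(trainScene$truth, 500L,
                              subSeed(config$seed, "scribbles"))
    clf <- fitPixelClassifier(feats, scr, subSeed(config$seed, "forest"))
    labs <- lapply(exp$scenes, function(tiles) lapply(tiles, function(tl) {
      cmapp <- predictClassMap(clf, tl$image)
      instancesFromClassMap(cmapp, config$pxSize, config$minArea,
                            config$borderPolicy)
    }))
    list(classifier = clf, labels = labs)
  })

  cells <- stageTry("measure", {
    rows <- list()
    for (sid in names(seg$labels)) {
      for (tl in seq_along(seg$labels[[sid]])) {
        pan <- measureLabelMap(seg$labels[[sid]][[tl]], config$pxSize)
        if (nrow(pan)) {
          pan$sample_id <- sid
          pan$tile <- tl
          rows[[length(rows) + 1L]] <- pan
        }
      }
    }
    do.call(rbind, rows)
  })
  perSample <- stageTry("measure",
    aggregateBySample(cells, expected = exp$table$sample_id))
  tab <- merge(exp$table, perSample, by = "sample_id", sort = TRUE)
  if (!is.null(out)) {
    write.csv(cells, file.path(out, "cells.csv"), row.names = FALSE)
    write.csv(tab, file.path(out, "sample_table.csv"), row.names = FALSE)
  }

  st <- stageTry("stats", {
    genes <- names(config$preset@geneEffects)
    folds <- lapply(genes, function(g) foldChange(tab, g))
    names(folds) <- genes
    cls <- setNames(exp$table$class, exp$table$sample_id)
    byArm <- split(cells, cls[cells$sample_id])
    names(byArm) <- c("control", "treated")[as.integer(names(byArm)) + 1L]
    pcm <- percentChangeMatrix(byArm, list(c("control", "treated")),
                               config$alpha)
    tests <- lapply(descriptorNames(), function(d)
      compareTwoGroups(byArm$control[[d]], byArm$treated[[d]], config$alpha))
    names(tests) <- descriptorNames()
    corSample <- correlogram(tab,
      variables = c("class", "donor", descriptorNames(), genes),
      alpha = config$alpha)
    list(foldChanges = folds, percentChange = pcm, descriptorTests = tests,
         correlogram = corSample)
  })

  fp <- stageTry("fingerprint", {
    genes <- names(config$preset@geneEffects)
    fm <- as.matrix(tab[, c(descriptorNames(), genes)])
    rownames(fm) <- tab$sample_id
    cimRes <- cim(fm, tab$class, config$linkage)
    z <- scaleCenter(fm)
    mdl <- plsdaFit(z, tab$class, ncomp = config$ncomp)
    mdl@classLabels <- c("control", "IL1b")
    list(cim = cimRes, plsda = mdl,
         ranking = rankDiscriminativeFeatures(mdl))
  })

  sig <- jsonlite::toJSON(list(seed = config$seed,
                               preset = config$preset@name,
                               table = round(as.matrix(
                                 tab[vapply(tab, is.numeric, TRUE)]), 8)),
                          digits = NA)
  manifest <- list(
    package = as.character(utils::packageVersion("ChondroMorph")),
    seed = config$seed, preset = config$preset@name,
    pxSize = config$pxSize, tilePx = config$tilePx,
    nSamples = nrow(tab), nCells = nrow(cells),
    cellsPerSample = as.vector(table(cells$sample_id)[tab$sample_id]),
    signature = paste0("sig-", sum(utf8ToInt(sig) *
                                     (seq_along(utf8ToInt(sig)) %% 97 + 1))))
  if (!is.null(out)) {
    jsonlite::write_json(
      list(manifest = manifest,
           foldChanges = lapply(st$foldChanges, function(f)
             list(mode = f$mode, mean = f$mean, sem = f$sem)),
           percentChange = as.data.frame(st$percentChange$percent),
           ranking = fp$ranking),
      file.path(out, "results.json"), auto_unbox = TRUE, digits = NA,
      dataframe = "rows")
    write.csv(fp$ranking, file.path(out, "plsda_ranking.csv"),
              row.names = FALSE)
  }
  list(table = tab, cells = cells, stats = st, cim = fp$cim,
       plsda = fp$plsda, ranking = fp$ranking, manifest = manifest,
       labels = seg$labels)
}
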