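#' Draw a ground-truth cell shape population
#'
#' Samples per-cell shape specifications for one experimental arm of a
#' preset. Cell bodies are ellipses: the major axis is drawn log-normally
#' around the preset's control mean and the aspect ratio log-normally
#' around the control mean aspect ratio; cytoplasmic processes (short
#' protrusions, <= 5 um) are attached with a Poisson-distributed count.
#' Treatment effects enter multiplicatively on the population means: the
#' area multiplier scales both axes by its square root, the aspect-ratio
#' multiplier scales the major axis up and the minor axis down
#' symmetrically (major x sqrt(area_eff * ar_eff), minor x
#' sqrt(area_eff / ar_eff)), so mean area, mean aspect ratio and mean
#' major-axis length are each controlled exactly. The circularity
#' multiplier modulates the protrusion rate (rate x circ_eff^-2): higher
#' circularity means fewer or smaller processes.
#'
#' @param preset an [EffectPreset].
#' @param nCells number of cells (>= 1).
#' @param seed integer seed; draws are bit-reproducible given the seed.
#' @param arm `"control"` or `"treated"`; control ignores the multipliers.
#' @param baselineOverride optional named numeric overriding entries of the
#'   preset's baseline (e.g. per-donor mean sizes).
#' @return data.frame with one row per cell: `cx`, `cy` (um, `NA` until
#'   placed by [renderScene()]), `major`, `minor` (um), `theta` (radians),
#'   `nucleusDiameter` (um) and a `protrusions` list-column of data.frames
#'   (`angle`, `length`, `width`).
#' @examples
#' pop <- generateShapePopulation(effectPreset("bovine_10ng"), 100, seed = 1)
#' mean(pop$major)  # close to the 35 um control mean
#' @export
generateShapePopulation <- function(preset, nCells, seed,
                                    arm = c("treated", "control"),
                                    baselineOverride = NULL) {
  stopifnot(is(preset, "EffectPreset"))
  arm <- match.arg(arm)
  nCells <- as.integer(nCells)
  if (is.na(nCells) || nCells < 1L) stop("nCells must be >= 1")
  b <- preset@baseline
  if (!is.null(baselineOverride)) b[names(baselineOverride)] <- baselineOverride
  eff <- if (arm == "treated") preset@morphEffects else
    setNames(rep(1, 7), descriptorNames())
  effMajor <- sqrt(eff[["area"]] * eff[["aspect_ratio"]])
  effAspect <- eff[["aspect_ratio"]]
  effProt <- eff[["circularity"]]^-2
  withSeed(seed, {
    sdMaj <- sqrt(log(1 + b[["cvMajor"]]^2))
    major <- rlnorm(nCells, log(b[["meanMajor"]] * effMajor) - sdMaj^2 / 2, sdMaj)
    sdAsp <- sqrt(log(1 + b[["cvAspect"]]^2))
    aspect <- pmax(1, rlnorm(nCells, log(b[["meanAspect"]] * effAspect) -
                               sdAsp^2 / 2, sdAsp))
    minor <- major / aspect
    theta <- runif(nCells, 0, pi)
    # nuclei scale with cell spread but have a physical floor (~8 um);
    # capped below the minor axis to keep the nucleus inside the body
    nuc <- pmin(0.9 * minor,
                pmax(8, b[["nucleusFrac"]] * minor * runif(nCells, 0.85, 1)))
    k <- rpois(nCells, b[["protrusionRate"]] * effProt)
    prot <- lapply(k, function(ki) {
      if (ki == 0L)
        return(data.frame(angle = numeric(0), length = numeric(0),
                          width = numeric(0)))
      data.frame(angle = runif(ki, 0, 2 * pi),
                 length = pmin(5, rlnorm(ki,
                   log(b[["protrusionMeanLength"]]) - 0.08, 0.4)),
                 width = rep(b[["protrusionWidth"]], ki))
    })
    out <- data.frame(cell = seq_len(nCells), cx = NA_real_, cy = NA_real_,
                      major = major, minor = minor, theta = theta,
                      nucleusDiameter = nuc)
    out$protrusions <- prot
    out
  })
}

# rasterize one cell (body + protrusions + nucleus) into the scene state
rasterizeCell <- function(state, shp, id, px) {
  a <- shp$major / 2; bb <- shp$minor / 2
  protr <- shp$protrusions[[1L]]
  maxProt <- if (nrow(protr)) max(protr$length) + max(protr$width) else 0
  rad <- a + maxProt + 2 * px
  nr <- nrow(state$lab); nc <- ncol(state$lab)
  i0 <- max(1L, floor((shp$cx - rad) / px)); i1 <- min(nr, ceiling((shp$cx + rad) / px))
  j0 <- max(1L, floor((shp$cy - rad) / px)); j1 <- min(nc, ceiling((shp$cy + rad) / px))
  if (i0 > i1 || j0 > j1) return(state)
  ii <- i0:i1; jj <- j0:j1
  xs <- (ii - 0.5) * px - shp$cx
  ys <- (jj - 0.5) * px - shp$cy
  dx <- rep(xs, times = length(jj))
  dy <- rep(ys, each = length(ii))
  ct <- cos(shp$theta); st <- sin(shp$theta)
  u <- dx * ct + dy * st
  v <- -dx * st + dy * ct
  r2 <- (u / a)^2 + (v / bb)^2
  inBody <- r2 <= 1
  intens <- numeric(length(u))
  intens[inBody] <- 0.6 + 0.4 * sqrt(pmax(0, 1 - r2[inBody]))
  if (nrow(protr)) {
    # half-width floor of 0.75 px keeps thin processes 4-connected after
    # rasterization
    hwFloor <- 0.75 * px
    for (q in seq_len(nrow(protr))) {
      phi <- protr$angle[q]
      p0 <- c(a * cos(phi), bb * sin(phi))
      nrm <- c(cos(phi) / a, sin(phi) / bb)
      nrm <- nrm / sqrt(sum(nrm^2))
      p1 <- p0 + protr$length[q] * nrm
      # distance of (u,v) to segment p0-p1
      wx <- u - p0[1]; wy <- v - p0[2]
      sx <- p1[1] - p0[1]; sy <- p1[2] - p0[2]
      ss <- sx^2 + sy^2
      t <- clamp01((wx * sx + wy * sy) / ss)
      d2 <- (wx - t * sx)^2 + (wy - t * sy)^2
      inProt <- d2 <= max(protr$width[q] / 2, hwFloor)^2
      intens[inProt & !inBody] <- 0.7
      inBody <- inBody | inProt
    }
  }
  if (!any(inBody)) return(state)
  rn2 <- (dx^2 + dy^2) / (shp$nucleusDiameter / 2)^2
  inNuc <- inBody & rn2 <= 1
  sub <- cbind(rep(ii, times = length(jj)), rep(jj, each = length(ii)))
  bidx <- sub[inBody, , drop = FALSE]
  state$lab[bidx] <- id
  state$class[bidx] <- 1L
  state$body[bidx] <- intens[inBody]
  state$nuc[bidx] <- 0  # later cell occludes earlier nuclei
  nidx <- sub[inNuc, , drop = FALSE]
  state$class[nidx] <- 2L
  state$nuc[nidx] <- 1 - 0.25 * rn2[inNuc]
  state
}

#' Render a shape population as a noisy two-channel tile
#'
#' Rasterizes cell bodies with protrusions (body channel) and nuclei
#' (nucleus channel) at the given pixel size, compositing overlapping cells
#' so that later cells occlude earlier ones, then applies Gaussian blur,
#' signal-dependent (photon-like) noise, additive read noise and a constant
#' background. The returned ground truth records per-pixel instance
#' ownership, the true pixel class map, and a per-cell descriptor panel
#' measured from the rasterized ground-truth masks with the same code path
#' as [measureLabelMap()].
#'
#' @param shapes shape population from [generateShapePopulation()]; rows
#'   with `NA` centers are placed uniformly at random in the field.
#' @param fieldSize numeric(2), field extent in um.
#' @param pixelSize microns per pixel (> 0).
#' @param noise noise model from [renderNoise()].
#' @param seed integer seed (placement and noise).
#' @param tileId tile identifier.
#' @return list with elements `image` ([ChannelImage]) and `truth`
#'   ([GroundTruthScene]).
#' @export
renderScene <- function(shapes, fieldSize, pixelSize, noise = renderNoise(),
                        seed = 1L, tileId = "tile") {
  if (pixelSize <= 0) stop("pixelSize must be > 0")
  nr <- as.integer(round(fieldSize[1] / pixelSize))
  nc <- as.integer(round(fieldSize[2] / pixelSize))
  if (nr < 4L || nc < 4L) stop("field too small for any cell")
  if (nrow(shapes) && max(shapes$major) > max(fieldSize))
    stop("field too small for any cell")
  withSeed(seed, {
    miss <- which(is.na(shapes$cx) | is.na(shapes$cy))
    if (length(miss)) {
      # monolayer placement: contact-inhibited cells touch but rarely
      # stack, so centers keep a soft minimum distance (0.7x the median
      # major axis); after 30 rejected draws a candidate is accepted
      # anyway so dense fields remain reachable
      dmin2 <- (0.7 * median(shapes$major))^2
      px <- numeric(0); py <- numeric(0)
      for (i in miss) {
        for (try in 1:30) {
          cx <- runif(1, 0, fieldSize[1]); cy <- runif(1, 0, fieldSize[2])
          if (!length(px) || min((px - cx)^2 + (py - cy)^2) >= dmin2) break
        }
        shapes$cx[i] <- cx; shapes$cy[i] <- cy
        px <- c(px, cx); py <- c(py, cy)
      }
    }
    state <- list(lab = matrix(0L, nr, nc), class = matrix(0L, nr, nc),
                  body = matrix(0, nr, nc), nuc = matrix(0, nr, nc))
    for (i in seq_len(nrow(shapes)))
      state <- rasterizeCell(state, shapes[i, ], i, pixelSize)
    state$lab <- relabelConsecutive(state$lab)
    body <- state$body; nuc <- state$nuc
    if (noise$blurSigma > 0) {
      body <- EBImage::gblur(body, noise$blurSigma)
      nuc <- EBImage::gblur(nuc, noise$blurSigma)
    }
    body <- noise$background + body
    nuc <- noise$background + nuc
    body <- body + rnorm(length(body), 0, noise$readSigma) +
      rnorm(length(body)) * noise$photonScale * sqrt(pmax(0, body))
    nuc <- nuc + rnorm(length(nuc), 0, noise$readSigma) +
      rnorm(length(nuc)) * noise$photonScale * sqrt(pmax(0, nuc))
    img <- new("ChannelImage",
               body = matrix(clamp01(as.numeric(body)), nr, nc),
               nucleus = matrix(clamp01(as.numeric(nuc)), nr, nc),
               pixelSize = pixelSize, tileId = tileId)
    panel <- measureLabelMap(state$lab, pixelSize)
    truth <- new("GroundTruthScene", shapes = shapes, labels = state$lab,
                 classMap = state$class, panel = panel,
                 pixelSize = pixelSize)
    list(image = img, truth = truth)
  })
}

#' Generate a ddPCR-like gene expression table
#'
#' Per-sample transcript concentrations (copies/uL) drawn log-normally
#' around gene-specific control means; treated samples' means are the
#' control means times the preset fold change. Samples are paired by donor:
#' expression carries a shared donor-level lognormal factor (CV
#' `exprDonorCV`) plus residual noise (CV `exprResidCV`), so per-donor fold
#' changes cancel the donor term, as in the paired study design.
#'
#' @param preset an [EffectPreset].
#' @param nPerGroup samples per arm (>= 2).
#' @param seed integer seed.
#' @return data.frame: `sample_id`, `donor`, `class` (0 control /
#'   1 treated), `dose`, then one copies/uL column per gene.
#' @examples
#' tab <- generateExpressionTable(effectPreset("human_oa"), 8, seed = 1)
#' head(tab)
#' @export
generateExpressionTable <- function(preset, nPerGroup = preset@nPerGroup,
                                    seed = 1L) {
  stopifnot(is(preset, "EffectPreset"))
  nPerGroup <- as.integer(nPerGroup)
  if (nPerGroup < 2L) stop("nPerGroup must be >= 2")
  if (any(preset@geneEffects < 0)) stop("negative fold change")
  genes <- names(preset@geneEffects)
  withSeed(seed, {
    sdD <- sqrt(log(1 + preset@exprDonorCV^2))
    sdR <- sqrt(log(1 + preset@exprResidCV^2))
    donorEff <- matrix(rlnorm(nPerGroup * length(genes), -sdD^2 / 2, sdD),
                       nPerGroup, length(genes), dimnames = list(NULL, genes))
    cls <- rep(c(0L, 1L), each = nPerGroup)
    donor <- rep(seq_len(nPerGroup), 2L)
    vals <- sapply(genes, function(g) {
      mu <- preset@geneControlMeans[[g]] *
        ifelse(cls == 1L, preset@geneEffects[[g]], 1) * donorEff[donor, g]
      mu * rlnorm(length(cls), -sdR^2 / 2, sdR)
    })
    out <- data.frame(sample_id = sprintf("S%02d", seq_along(cls)),
                      donor = donor, class = cls, dose = preset@dose)
    cbind(out, as.data.frame(vals))
  })
}

#' Build a full synthetic experiment
#'
#' Emits `nPerGroup` control and `nPerGroup` treated samples. Each sample
#' receives one or more rendered tiles at the preset seeding density and a
#' gene expression row; treatment is coded 0/1. Donor-paired structure:
#' each treated sample shares its donor with one control sample, and a
#' donor-level lognormal factor (CV `morphDonorCV`) perturbs the donor's
#' mean cell size (and, more weakly, aspect ratio) identically in both
#' arms. For the human preset, the shipped macroscopic grades
#' ([donorGrades()]) are attached per donor.
#'
#' @param preset an [EffectPreset].
#' @param seed integer seed; the whole experiment is reproducible from it.
#' @param nPerGroup samples per arm (paper default 8).
#' @param tilePx integer(2), tile size in px.
#' @param pxSize microns per pixel.
#' @param density seeding density in cells/cm^2 (defaults to the preset's).
#' @param noise noise model from [renderNoise()].
#' @param tilesPerSample tiles rendered per sample (>= 1).
#' @return list with `table` (the sample table: metadata, living-cell
#'   count, grades, gene copies/uL) and `scenes` (per sample, a list of
#'   `list(image, truth)` tiles).
#' @export
buildExperiment <- function(preset, seed = 1L, nPerGroup = preset@nPerGroup,
                            tilePx = c(384L, 384L), pxSize = 2,
                            density = preset@seedingDensity,
                            noise = renderNoise(), tilesPerSample = 1L) {
  stopifnot(is(preset, "EffectPreset"))
  expr <- generateExpressionTable(preset, nPerGroup, subSeed(seed, "expr"))
  fieldUm <- tilePx * pxSize
  cellsPerTile <- max(1L, as.integer(round(density / 1e8 * prod(fieldUm))))
  donorFacs <- withSeed(subSeed(seed, "donor-morph"), {
    sdM <- sqrt(log(1 + preset@morphDonorCV^2))
    data.frame(size = rlnorm(nPerGroup, -sdM^2 / 2, sdM),
               aspect = rlnorm(nPerGroup, -(sdM / 2)^2 / 2, sdM / 2))
  })
  b <- preset@baseline
  scenes <- vector("list", nrow(expr))
  names(scenes) <- expr$sample_id
  for (i in seq_len(nrow(expr))) {
    d <- expr$donor[i]
    arm <- if (expr$class[i] == 1L) "treated" else "control"
    tiles <- vector("list", tilesPerSample)
    for (tl in seq_len(tilesPerSample)) {
      s <- subSeed(seed, paste0("tile-", expr$sample_id[i], "-", tl))
      pop <- generateShapePopulation(preset, cellsPerTile, s, arm = arm,
        baselineOverride = c(meanMajor = b[["meanMajor"]] * donorFacs$size[d],
                             meanAspect = b[["meanAspect"]] * donorFacs$aspect[d]))
      tiles[[tl]] <- renderScene(pop, fieldUm, pxSize, noise,
                                 seed = subSeed(s, "render"),
                                 tileId = sprintf("%s-t%d", expr$sample_id[i], tl))
    }
    scenes[[i]] <- tiles
  }
  tab <- expr
  tab$density <- density
  tab$grade <- if (preset@name == "human_oa")
    donorGrades()$grade[tab$donor] else NA_real_
  tab$living_cells <- withSeed(subSeed(seed, "living"), {
    round(rlnorm(nrow(tab), log(5e4) - 0.01, 0.15))
  })
  ord <- c("sample_id", "donor", "class", "dose", "density", "grade",
           "living_cells", names(preset@geneEffects))
  list(table = tab[, ord], scenes = scenes, preset = preset,
       pixelSize = pxSize, cellsPerTile = cellsPerTile)
}
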