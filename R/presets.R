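#' Shipped experimental effect presets
#'
#' Returns an [EffectPreset] bundling the study conditions of one of the
#' emulated experiments. The per-descriptor multipliers and per-gene fold
#' changes are the printed population-level effects of persistent IL-1beta
#' exposure; control-level morphology parameters and within-group
#' variability are the package's own stated choices (see the methods
#' vignette).
#'
#' Available presets:
#' \describe{
#'   \item{`human_oa`}{Human OA chondrocytes, 0.1 ng/ml IL-1beta,
#'     9375 cells/cm^2, 8 donor pairs. Morphology effects: area 0.87,
#'     width 0.87, length 1.02, circularity 1.02, aspect ratio 1.17,
#'     roundness 0.87, solidity 1.00. Gene fold changes: COL1A2 1,
#'     COL2A1 0.1, SOX9 0.7, ACAN 0.2, IL-6 82, IL-8 147.}
#'   \item{`bovine_10ng`}{Healthy bovine chondrocytes, 10 ng/ml IL-1beta,
#'     3000 cells/cm^2 (low density), 8 samples per arm from 3 cows.
#'     Morphology effects: area 1.10, length 1.05, width 1.10,
#'     circularity 1.15, roundness 1.03, solidity 1.006, aspect ratio
#'     0.99; control mean major axis 35 um. Gene fold changes: COL1A2 1,
#'     COL2A1 0.5, IL-6 50, IL-8 22; IL-8 control expression is near zero
#'     so fold-change reporting switches to copies/uL.}
#'   \item{`null`}{All multipliers 1; used for type-I-error checks.}
#' }
#'
#' @param name preset name.
#' @return an [EffectPreset].
#' @examples
#' effectPreset("human_oa")
#' @export
effectPreset <- function(name = c("human_oa", "bovine_10ng", "null")) {
  name <- match.arg(name)
  d <- descriptorNames()
  base <- function(meanMajor, meanAspect)
    c(meanMajor = meanMajor, meanAspect = meanAspect,
      cvMajor = 0.25, cvAspect = 0.18,
      protrusionRate = 1.5, protrusionMeanLength = 3,
      protrusionWidth = 2.5, nucleusFrac = 0.5)
  if (name == "human_oa") {
    new("EffectPreset", name = name,
        morphEffects = setNames(c(0.87, 1.02, 0.87, 1.02, 1.17, 0.87, 1.00), d),
        geneEffects = c(COL1A2 = 1, COL2A1 = 0.1, SOX9 = 0.7, ACAN = 0.2,
                        IL6 = 82, IL8 = 147),
        geneControlMeans = c(COL1A2 = 180, COL2A1 = 1200, SOX9 = 90,
                             ACAN = 350, IL6 = 2, IL8 = 1.5),
        baseline = base(40, 2.0), nPerGroup = 8L, seedingDensity = 9375,
        dose = "0.1", exprDonorCV = 0.25, exprResidCV = 0.15,
        morphDonorCV = 0.08)
  } else if (name == "bovine_10ng") {
    new("EffectPreset", name = name,
        morphEffects = setNames(c(1.10, 1.05, 1.10, 1.15, 0.99, 1.03, 1.006), d),
        geneEffects = c(COL1A2 = 1, COL2A1 = 0.5, IL6 = 50, IL8 = 22),
        geneControlMeans = c(COL1A2 = 150, COL2A1 = 2500, IL6 = 1.5,
                             IL8 = 0.2),
        baseline = base(35, 1.7), nPerGroup = 8L, seedingDensity = 3000,
        dose = "10", exprDonorCV = 0.25, exprResidCV = 0.15,
        morphDonorCV = 0.08)
  } else {
    new("EffectPreset", name = name,
        morphEffects = setNames(rep(1, 7), d),
        geneEffects = c(COL1A2 = 1, COL2A1 = 1, SOX9 = 1, ACAN = 1,
                        IL6 = 1, IL8 = 1),
        geneControlMeans = c(COL1A2 = 180, COL2A1 = 1200, SOX9 = 90,
                             ACAN = 350, IL6 = 2, IL8 = 1.5),
        baseline = base(38, 1.8), nPerGroup = 8L, seedingDensity = 9375,
        dose = "0", exprDonorCV = 0.25, exprResidCV = 0.15,
        morphDonorCV = 0.08)
  }
}

#' Macroscopic cartilage grades of the human donors
#'
#' The 3-point macroscopic damage grades of the eight human OA cartilage
#' explants (grade 1 intact ... 3 severe OA), shipped verbatim as the
#' default human donor metadata; their mean +/- SD rounds to 1.8 +/- 0.5.
#'
#' @return data.frame with columns `donor` and `grade`.
#' @examples
#' g <- donorGrades()
#' round(mean(g$grade), 1)
#' @export
donorGrades <- function() {
  data.frame(donor = 1:8,
             grade = c(2, 1.5, 2.5, 1, 2, 2, 1.5, 2))
}

#' Default rendering noise model
#'
#' Noise parameters used by [renderScene()]: constant background level,
#' Gaussian blur sigma (px), signal-dependent (photon-like) noise scale and
#' additive Gaussian read noise, on the [0, 1] intensity scale. Defaults
#' are chosen so that the default pixel classifier reaches at least 95
#' percent pixel accuracy on rendered scenes (verified by the test suite).
#'
#' @param background numeric, background offset.
#' @param photonScale numeric, SD of signal-dependent noise at full signal.
#' @param blurSigma numeric, Gaussian blur sigma in px.
#' @param readSigma numeric, SD of additive Gaussian noise.
#' @return named list.
#' @export
renderNoise <- function(background = 0.08, photonScale = 0.05,
                        blurSigma = 1.0, readSigma = 0.02) {
  list(background = background, photonScale = photonScale,
       blurSigma = blurSigma, readSigma = readSigma)
}
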