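---
title: "Single-cell morphometric fingerprinting: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-cell morphometric fingerprinting: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ChondroMorph)
```

## The problem

Articular chondrocytes change shape when their phenotype changes:
differentiated cells are round, while dedifferentiated or inflamed cells
(for instance after persistent IL-1&beta; exposure) spread, elongate, and
grow cytoplasmic processes. ChondroMorph implements a complete pipeline
that turns two-channel fluorescence images (a calcein-like cell-body stain
and a Hoechst-like nucleus stain) into per-cell shape descriptors,
combines them with ddPCR-style absolute gene expression (copies/&micro;L),
and asks which features discriminate control from inflammatory
populations. Because no public imaging data accompany the study design the
package emulates, a first-class synthetic-data module generates ground-truth
scenes and expression tables with the printed effect structure, so that
every stage — segmentation, morphometry, statistics, fingerprinting — is
testable end to end.

## The synthetic generator

`generateShapePopulation()` draws cells as ellipses with protrusions:

* major axis: log-normal around the preset's control mean
  (`meanMajor`, 35 &micro;m for the bovine preset — the control value the
  pipeline must recover — and 40 &micro;m for the human-OA preset, a
  stated choice);
* aspect ratio: log-normal around `meanAspect` (1.7 bovine, 2.0 human),
  truncated at 1; the minor axis is the quotient;
* protrusions ("cytoplasmic processes"): Poisson count (rate 1.5),
  length log-normal capped at 5 &micro;m, width 2.5 &micro;m;
* nucleus: a disc scaled to the minor axis with a physical floor of
  8 &micro;m, capped below the minor axis.

Treatment effects are multiplicative on population means. The preset
stores the full printed seven-descriptor effect vector, but only three
generative controls exist: the **area** multiplier scales both axes by its
square root, the **aspect-ratio** multiplier scales the major axis up and
the minor axis down symmetrically (so mean area, mean aspect ratio and
mean major length are each controlled exactly and independently), and the
**circularity** multiplier modulates the protrusion rate
(rate &times; circ^-2^: more circular means fewer processes). Length,
width, roundness and solidity effects are then emergent; the printed panel
is internally redundant (length &times; width &asymp; area,
1/aspect-ratio &asymp; roundness), and the emergent values land close to
the printed ones. Circularity and solidity are the least directly
controlled: elongation lowers measured circularity while fewer protrusions
raise it, and their net through-pipeline change need not match the printed
percentage — the recovery tests therefore target area, roundness, aspect
ratio and length.

Within-group variability is not printed in the emulated study (only
box-plot percentiles), so it is a stated, overridable choice: CV 0.25 on
the size draw and 0.18 on the aspect-ratio draw; expression CV 0.3,
decomposed as donor CV 0.25 &times; residual CV 0.15. The decomposition
matters: samples are donor-paired, so per-donor fold changes cancel the
donor term and the arithmetic mean paired fold inflates only by
exp(&sigma;&sup2;~resid~) &asymp; 1.02 over the preset fold, rather than
exp(&sigma;&sup2;~total~) &asymp; 1.09 for an unpaired design.
`buildExperiment()` additionally applies a donor-level log-normal factor
(CV 0.08) to each donor's mean cell size in both arms; without any
between-donor morphology variance the sample-level clustering and PLS-DA
would be degenerate.

`renderScene()` rasterizes cells back-to-front with later cells occluding
earlier ones (labels, classes and nucleus intensity alike), applies a
radial intensity falloff, Gaussian blur (&sigma; = 1 px), a constant
background (0.08), signal-dependent photon-like noise (scale 0.05) and
Gaussian read noise (SD 0.02) on a [0, 1] scale. Cell placement follows a
monolayer model: centers keep a soft minimum distance of 0.7 &times; the
median major axis (contact-inhibited cells touch but rarely stack), with
the constraint released after 30 rejected draws. The per-cell true panel
stored in the ground truth is computed from the rasterized masks by the
same `measureLabelMap()` code path used downstream, so truth and
measurement are comparable exactly.

What the generator does **not** emulate: optical point-spread physics,
ddPCR droplet Poisson statistics, cell migration or temporal dynamics,
uneven illumination, and real protrusion morphology (curved, branched).
Passing recovery tests therefore show that the pipeline is unbiased for
this image model at these noise levels, not that it is unbiased on any
real microscope's output.

## Segmentation

`computeFeatureStack()` builds, per channel, the raw intensity plus
Gaussian-smoothed intensity, gradient magnitude and Laplacian at
&sigma; &isin; {1, 2, 4} px — 20 features for two channels. The feature
family of the original trainable-segmentation tool is not published; this
stack is our stated, configurable choice.

`fitPixelClassifier()` trains a probability forest (50 randomized trees,
deterministic given its seed) on scribble-annotated pixels of the three
classes background / cytosol / nucleus. The contract is only "probabilistic
three-class pixel classifier"; the family is pluggable.
`scribblesFromTruth()` emulates a practiced annotator: half of the
background and cytosol scribbles are placed within 2 px of the cell
boundary, which anchors the decision boundary on the blurred cell rim.
With uniform-only scribbles the boundary is extrapolated and the
foreground dilates by roughly half a pixel — enough to bias absolute areas
by several percent.

`predictClassMap()` assigns the per-pixel argmax class with ties broken
toward background. `instancesFromClassMap()` separates instances by
flooding the foreground from markers with `EBImage::propagate` over the
foreground distance transform: markers are 4-connected nucleus-class
components of at least 9 px; foreground blobs with no marker are kept as
single instances (logged, not discarded); instances under 50 &micro;m&sup2;
(debris) are removed; border-touching instances are removed by default
because their descriptors are truncated. Flooding is deterministic, so the
label map is reproducible bit-for-bit.

## Morphometry

`measureRegion()` computes, in physical units: area (pixel count &times;
px&sup2;); length and width as the major/minor axes of the ellipse with
equal second central moments (with the 1/12 px&sup2; pixel-extent term);
perimeter by the Proffitt&ndash;Rosen weighted chain code (orthogonal step
0.948, diagonal 1.340) over the 8-connected boundary chain — digitized
perimeters otherwise systematically inflate and deflate circularity;
circularity 4&pi;A/P&sup2; and roundness 4A/(&pi;L&sup2;), both clamped at
1 because discretization can push them slightly above; aspect ratio L/W;
and solidity A over the area of the convex hull taken on the pixel
*corners*, so that convex rasterized shapes yield solidity exactly 1. Note
that the boundary chain runs through boundary-pixel centers and
underestimates the perimeter of small objects; at the default 2 &micro;m/px
the circularity of small near-circular cells saturates at the clamp, which
is one reason circularity is the least trusted descriptor here.

Aspect ratio measures elongation (length relative to width) and is kept
distinct from length itself: a cell can lengthen without elongating if its
width grows in proportion.

## Statistics

`compareTwoGroups()` gates on normality and then applies Student's t-test
(pooled variance) or the Mann&ndash;Whitney rank-sum test with
tie-corrected normal approximation. The gate is the Lilliefors variant of
the Kolmogorov&ndash;Smirnov test because the plain KS test with estimated
mean and SD is anti-conservative; groups too small for the gate (n &lt; 4)
or with zero variance fall through to the rank test. `multiGroupRanks()`
is the Kruskal&ndash;Wallis rank ANOVA with Dunn's all-pairs z statistics
on mean ranks (tie-corrected pooled variance), supporting unequal group
sizes. No multiple-testing correction is applied by default, matching the
p &lt; 0.05 convention of the emulated analysis; a Holm option exists.

`foldChange()` implements the each-control-set-to-1 convention: per-donor
treated/control ratios, summarized as mean &plusmn; SEM. When control
expression is essentially absent (median control below 0.5 copies/&micro;L)
the ratio is meaningless and the gene is reported in raw copies/&micro;L
instead (the bovine IL-8 situation). `percentChangeMatrix()` emits
100 &times; (mean~b~ &minus; mean~a~)/mean~a~ per descriptor per ordered
condition pair with significance flags. `correlogram()` dispatches per
pair: Spearman if either variable is categorical/ordinal (treatment class
coded 0/1, donor, macroscopic grade), Pearson otherwise. In single-cell
correlograms the sample's treatment class is broadcast to its cells; the
emulated analysis does not state how it mixed levels, and this is our
reading.

## Fingerprinting

`cim()` z-scores features (SD units away from the feature mean) and
clusters rows and columns by Euclidean-distance hierarchical clustering,
complete linkage by default (the linkage of the referenced toolkit is not
stated; average and Ward are available). A 2-cluster row cut is
cross-tabulated against the condition classes.

`plsdaFit()` is a from-scratch NIPALS PLS-DA against a single 0/1 class
column, both X and y centered: per component w &prop; X'y~c~ (unit norm),
t = Xw, p = X't/t't, q = y't/t't, then deflation of X and y.
Initialization is deterministic (the centered response); convergence
tolerance 1e-10, at most 500 inner iterations — with a univariate response
the inner loop converges in one pass and the component-1 weight equals the
normalized feature&ndash;class covariance exactly, which the tests pin to
1e-10. Scores are mutually orthogonal by construction (checked to 1e-8)
and with ncomp = min(n&minus;1, p) the centered X is reconstructed from
scores &times; loadings to 1e-6. `rankDiscriminativeFeatures()` reads
importance from the component-1 X-loading magnitudes and assigns each
feature to the class its sign points toward; flipping the 0/1 coding flips
assignments but not the ranking. Feature rankings of the *leading*
features (the top treated-class expression genes, the top control-side
descriptor) are stable across seeds for the shipped presets; mid-ranked
features with near-tied loadings can swap order between seeds at n = 16
samples, which is inherent to the sample size, not to the fitting.

## Numerical and design choices

* Pixel size defaults to 2 &micro;m/px (10&times; imaging downsampled, as
  in the emulated workflow); recovery experiments use 512&times;512 px
  tiles of 160 cells and the default experiment 384&times;384 px tiles at
  the preset seeding density (9375 cells/cm&sup2; human, 3000 bovine).
* The recovery experiment (`morphologyRecovery()`) renders both arms with
  common random substreams: the treated arm re-uses the control arm's
  draws with multipliers applied, so arm contrasts are estimated without
  independent sampling noise and the run is deterministic given one seed.
* Problem sizes: the test suite renders roughly 700 cells per arm per
  preset and the acceptance script 1600 per arm; expression recovery
  averages 200 seeded tables of 8 donor pairs. These sizes put Monte-Carlo
  error comfortably below the tolerances being checked.
* Ties at watershed ridges are resolved by the deterministic flooding of
  `propagate`; coordinates are 0-based row-major in the boundary code and
  masks are 4-connected throughout.
* All randomness flows from one master seed through named substreams
  (`subSeed`), and every generator restores the caller's RNG state.

## Known limitations

* Absolute morphometry carries a small positive bias (about 1&ndash;3% on
  mean length at default noise): protrusions and pixel-extent terms enter
  the moments, and segmentation resolves contact zones by distance rather
  than by the true occlusion order. Group *contrasts* are unaffected to
  first order, which is why percent-change recovery is tight while
  absolute recovery is tested at a looser 5%.
* Circularity of small, nearly round cells saturates at the clamp (see
  above); solidity changes are tiny by construction and dominated by
  protrusion rendering.
* The classifier is trained per experiment on one control tile; no
  transfer across imaging conditions is attempted, and none is claimed.
* The pipeline is 2D; volume effects of inflammatory swelling are visible
  only through projected area.
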