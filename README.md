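# ChondroMorph

Single-cell morphometric fingerprinting of chondrocyte phenotype.

Chondrocytes — the resident cells of articular cartilage — signal their
phenotypic state through their shape: differentiated cells are round,
while inflamed or dedifferentiating cells spread, elongate and grow
cytoplasmic processes. ChondroMorph is an R package for researchers who
want to quantify that relationship: it segments two-channel fluorescence
images (calcein-like cell body + Hoechst-like nucleus) with a trainable
three-class pixel classifier, separates touching cells with a
marker-based watershed seeded on nuclei, measures a seven-descriptor
shape panel per cell, and combines the morphology with ddPCR-style
absolute gene expression (copies/µL) to identify the *morphological
fingerprint* that discriminates control from inflammatory (IL-1β-treated)
populations.

The shape panel, for a cell of area *A*, perimeter *P*, and
moment-equivalent ellipse axes *L* (major) and *W* (minor):

| descriptor | definition |
|---|---|
| area | *A* (µm²) |
| length | *L* (µm) |
| width | *W* (µm) |
| circularity | 4π·*A*/*P*² |
| aspect ratio | *L*/*W* |
| roundness | 4·*A*/(π·*L*²) |
| solidity | *A* / area of convex hull |

The multivariate stage z-scores sample-level features, draws a clustered
image map (Euclidean-distance hierarchical clustering of samples and
features, color scale in SD units), and fits a from-scratch NIPALS
PLS-DA against the 0/1 treatment class; component-1 loadings rank each
feature's discriminative importance and their signs assign it to the
class it marks.

Because the emulated study deposits no images, a first-class synthetic
module generates ground-truth scenes and expression tables with the
published effect structure (for example, IL-6 ×82 and IL-8 ×147 in
human OA chondrocytes; −13% area and +17% aspect ratio under 0.1 ng/ml
IL-1β), so the entire pipeline is testable offline, end to end.

## Worked example

```r
library(ChondroMorph)

cfg <- pipelineConfig("human_oa", seed = 11)
res <- runPipeline(cfg)

res$ranking[1:5, ]
#>        feature    loading importance   class
#> 1       COL2A1 -0.3386068  0.3386068 control
#> 2 aspect_ratio  0.3379225  0.3379225    IL1b
#> 3    roundness -0.3377572  0.3377572 control
#> 4          IL8  0.3346319  0.3346319    IL1b
#> 5          IL6  0.3205425  0.3205425    IL1b

res$cim@crosstab
#>        class
#> cluster 0 1
#>       1 8 0
#>       2 0 8

res$stats$foldChanges$IL6$mean
#> [1] 88.64054
round(res$stats$percentChange$percent, 1)
#>              treated vs control
#> area                      -11.1
#> length                      1.5
#> width                     -11.5
#> circularity                -5.6
#> aspect_ratio               14.9
#> roundness                 -12.9
#> solidity                  -1.2
```

Reading the output: the 16 synthetic samples (8 donor-paired
control/treated pairs) cluster perfectly by treatment in the CIM; the
PLS-DA fingerprint marks IL-8 and IL-6 expression as the strongest
IL-1β indicators and roundness as the strongest control-side shape
descriptor, with elevated aspect ratio marking treated cells — the
inflammatory elongation signature. The per-gene fold change (each
control set to 1, donor-paired ratios, mean ± SEM) recovers the ×82
IL-6 preset within sampling error, and the percent-change table shows
the treated cells smaller, less round and more elongated.

Individual stages are ordinary functions: `generateShapePopulation()` /
`renderScene()` / `generateExpressionTable()` (synthesis),
`computeFeatureStack()` / `fitPixelClassifier()` / `predictClassMap()` /
`instancesFromClassMap()` (segmentation), `measureRegion()` /
`measureLabelMap()` / `aggregateBySample()` (morphometry),
`compareTwoGroups()` / `multiGroupRanks()` / `foldChange()` /
`percentChangeMatrix()` / `correlogram()` (statistics), and
`scaleCenter()` / `cim()` / `plsdaFit()` /
`rankDiscriminativeFeatures()` (fingerprinting). A thin command-line
wrapper lives in `inst/scripts/chondromorph.R`
(`simulate` / `run-all` subcommands). The methods vignette
(`vignettes/methods.Rmd`) documents the models, parameter choices and
limitations.

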