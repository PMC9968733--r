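Package: ChondroMorph
Title: Single-Cell Morphometric Fingerprinting of Chondrocyte Phenotype
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Trainable three-class pixel segmentation of two-channel
    fluorescence images, marker-based watershed instance separation, a
    seven-descriptor single-cell shape panel (area, length, width,
    circularity, aspect ratio, roundness, solidity), population statistics
    with normality-gated two-group tests and rank-based multi-group tests,
    class-coded correlograms, clustered image maps, and NIPALS PLS-DA
    loading-based feature importance for discriminating control versus
    inflammatory (IL-1beta) chondrocyte phenotypes. A synthetic-data module
    renders calcein/Hoechst-like chondrocyte scenes with ground truth and
    generates droplet-digital-PCR-like expression tables so the whole
    pipeline is testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    graphics,
    grDevices,
    utils,
    EBImage,
    ranger,
    tiff,
    nortest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    optparse,
    withr
biocViews: CellBiology, Classification, Clustering, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
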