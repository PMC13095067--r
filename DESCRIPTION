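Package: CardioPheno
Title: Quantitative Phenotyping of Laminopathy Cardiomyocyte Models
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Image, trace and expression analytics for cardiomyocyte disease
    models: concentric-bin radial profiling of painted chromosome territories
    in nuclear masks (distance-transform binning, min-max normalized heatmap
    matrices, two-way ANOVA group comparison), nuclear morphometrics (area,
    perimeter, circularity, solidity, maximal Feret diameter),
    contraction and ratiometric-calcium trace metrics (beat segmentation,
    contraction and relaxation times, beat-to-beat heterogeneity index,
    diastolic time to 90 percent baseline return, Hill-fit EC50 of the
    force-calcium relationship), and chromosome-level summaries of
    differentially expressed genes. Includes seeded generators for synthetic
    nuclei with territory blobs at controlled radial positions, paced beat
    traces, calcium dose-response curves and differential-expression tables,
    so the whole pipeline is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    EBImage,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
biocViews: CellBiology, FISH, Visualization, StatisticalMethod, GeneExpression
Config/testthat/edition: 3
RoxygenNote: 7.3.3
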