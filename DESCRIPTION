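Package: atlassel
Title: Atlas Pre-Selection for Multi-Atlas Brain MRI Segmentation
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Ranks an atlas library against a target brain MR image and
    selects the top-k atlases before label fusion, implementing
    coarse-segmentation Dice criteria (four-label 4L and lateral-ventricle
    LV), a normalized mutual-information criterion, and a seeded random
    baseline. Includes a registration-free multi-atlas segmentation core
    (majority and similarity-weighted label voting on a common voxel grid),
    hierarchical Level A/B/C evaluation with per-structure Dice and
    poor-outcome ratios, a fast k-means 7-label coarse tissue segmenter,
    and a synthetic brain-phantom library generator so every stage is
    testable without clinical data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    jsonlite,
    withr,
    optparse
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Software, Segmentation, Preprocessing
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'atlassel-package.R'
    'cli.R'
    'coarseseg.R'
    'evaluate.R'
    'fusion.R'
    'hierarchy.R'
    'methods.R'
    'phantom.R'
    'preselect.R'
    'similarity.R'
    'utils.R'
    'volio.R'
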