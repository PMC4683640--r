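Package: spermatoscope
Title: Computational Phenotyping of Male Reproductive Traits in Inbred Strain Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for strain-survey phenotyping of male
    reproduction. Detects seminiferous-tubule cross-section centers in
    PAS/hematoxylin testis sections with a random-forest classifier over
    local color-histogram features, estimates tubule radii from
    nearest-neighbour distances, and computes section-level histology
    metrics including seminiferous epithelium length and abnormality
    counts. Computes computer-assisted sperm analysis (CASA) kinematic
    parameters (VAP, VSL, VCL, ALH, BCF, STR, LIN) from sperm head
    tracks and classifies motile sperm into five motility patterns
    (progressive, intermediate, hyperactivated, slow, weakly motile)
    with a cascade of support vector machines. Provides the strain-level
    statistics of such surveys: modified z-scores with outlier
    classification, broad-sense heritability, pairwise-complete Pearson
    correlations, and one-/two-way ANOVA with a strain-by-age
    interaction. Synthetic generators for histology sections, sperm
    tracks and phenotype tables with known ground truth make every stage
    testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    ranger,
    e1071,
    EBImage,
    png,
    jsonlite,
    yaml,
    readr,
    tibble
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
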