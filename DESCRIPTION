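Package: heatPheno
Title: High-Throughput Heat-Stress Phenotyping Analysis for Arabidopsis Rosettes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for image-based heat-stress
    phenotyping of Arabidopsis rosettes. Generates a full factorial
    heat-stress experiment (genotype x treatment x replicate, daily imaging)
    with kinetic chlorophyll-fluorescence light curves, parametric rosette
    masks and thermal rasters; derives the standard PAM fluorescence
    parameters (Fv/Fm, QY', NPQ, qN, qP, Fq') and rosette morphology traits
    (area, perimeter, compactness, roundness, eccentricity, isotropy,
    rotational mass symmetry, slenderness of leaves); provides temporal
    group comparisons, genotype-by-treatment interaction models, Pearson
    correlograms and cross-time trait correlations; and ranks traits by an
    L1-regularized logistic genotype classifier with grouped, stratified
    cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tools,
    EBImage,
    png,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Phenotyping, ImageAnalysis, Classification, Regression
RoxygenNote: 7.3.3
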