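Package: aceforest
Title: Autocorrelation-Competition-Error Models for Forest Genetics Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of individual-tree forest genetics
    trials with explicit spatial structure. Generates incomplete-block
    single-tree-plot trial layouts, half-sib or full-sib pedigrees, and
    phenotypes with known additive-genetic, site (separable AR1xAR1), and
    inter-tree competition structure, plus a synthetic canopy height model
    (CHM). Processes a CHM into per-tree growing spaces, crowns, and nine
    crown morphology metrics via pit closing and marker-controlled watershed
    segmentation; computes distance-weighted Hegyi-type competition indices
    (three formulations, two neighbourhood definitions); and fits the four
    individual-tree REML mixed models B, BA, BC, and BAC, combining a
    pedigree additive effect, design random effects, a separable AR1xAR1
    correlated residual with nugget, and a standardized competition
    covariate. Model comparison uses likelihood-ratio tests with
    boundary-corrected chi-square mixtures, AIC/BIC, narrow-sense
    heritability with delta-method standard errors, and percentage
    improvements in heritability and residual variance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
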