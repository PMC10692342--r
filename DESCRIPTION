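Package: heatnorm
Title: Reaction-Norm Models for Prenatal Heat Stress Effects on Calf Birth Weight
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying time-lagged (prenatal) heat-stress effects
    on calf birth weight in dairy cattle. Builds weekly temperature-humidity
    index (THI) covariates and their first principal component over late
    gestation from hourly weather records, applies standard phenotype edits,
    constructs pedigree (A), genomic (G) and single-step (H) relationship
    matrices with SNP quality control, fits fixed-regression and maternal
    reaction-norm mixed models by average-information REML, and derives
    heritabilities, variance functions and genetic correlations along the
    heat-load gradient. Includes a fully parameterised synthetic-data
    generator (weather, pedigree, genotypes, phenotypes) so that every stage
    of the pipeline can be exercised and validated against known generating
    parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    lme4,
    MASS,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
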