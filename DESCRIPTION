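Package: growthqtl
Title: Functional QTL Mapping and Genomic Prediction for Longitudinal
    Growth Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for longitudinal canopy-height (or other
    growth-trait) data in biparental inbred-line populations.  Fits
    spatially adjusted per-time-point mixed models with AR1xAR1 field
    correlation, a rank-1 factor-analytic temporal covariance for
    genotype effects, B-spline smoothing with cross-validated basis
    selection and functional principal component analysis of the growth
    curves.  QTL mapping by Haley-Knott regression at individual time
    points (interval and composite interval mapping) and functionally
    across time points (multivariate HKLOD, maximum MLOD and average
    SLOD statistics) with permutation thresholds and penalized-LOD
    stepwise multiple-QTL search.  Includes data-perturbation power
    simulation, GBLUP genomic prediction with VanRaden kinship, QTL
    fixed covariates and Scott-Knott scenario comparison, and a
    synthetic-trial generator with known genetic architecture for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    splines,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
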