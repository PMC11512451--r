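Package: specTune
Title: Sequence-to-Function Regression and Spectral Tuning-Site Analysis for Opsins
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genotype-to-phenotype analysis of visual opsins:
    reconstruction of mutant and chimeric sequences from machine-readable
    mutation notation, one-hot encoding of amino-acid alignments with an
    unseen-residue rule, cross-validated training and ranking of a pluggable
    regressor suite for predicting the wavelength of peak absorbance
    (lambda-max), position-importance reports mapped to bovine-rhodopsin
    coordinates, intragenic-epistasis analysis via additive expectations,
    Brownian-motion phylogenetic imputation of missing tip phenotypes,
    learning-curve analysis with AIC-based nonlinear model selection, and a
    fully seeded synthetic-data generator that provides ground truth for
    every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    Biostrings,
    ape,
    glmnet,
    ranger,
    xgboost,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
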