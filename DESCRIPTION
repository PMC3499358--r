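Package: viroquant
Title: Quantitative Genetics of Virus Resistance in Inbred Fly Line Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative-genetic analysis of host resistance to
    viral infection in panels of homozygous inbred lines (DGRP-style designs).
    Provides a synthetic-data generator for line-by-site genotype panels and
    vial-structured phenotypes; Bayesian MCMC estimation of variance
    components, heritability on the observed and logit scales, coefficients of
    genetic variation and genetic correlations; line-mean genome-wide
    association scans with permutation-derived genome-wide significance
    thresholds, permutation QQ expectations, conditional scans and joint
    multi-SNP models; and conversion of locus effects into additive genetic
    variance (2pqa^2), proportion of heritability explained, and
    outbred-population projections under dominance scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4,
    glmmTMB,
    vcfR,
    optparse
Config/testthat/edition: 3
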