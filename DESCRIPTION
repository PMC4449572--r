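Package: rrgwas
Title: Single-Step GWAS on Legendre Random-Regression Coefficients for
    Longitudinal Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fits random-regression GBLUP models for longitudinal traits
    (growth and feed-intake trajectories) using order-2 Legendre polynomial
    covariance functions, a blended pedigree/genomic (single-step H matrix)
    relationship structure and EM-REML variance components.  SNP effects are
    obtained by iteratively reweighted back-solving of the animal-specific
    coefficient breeding values; QTL regions are located by the variance of
    10-SNP sliding-window genomic breeding values and tested against a
    bootstrap null in which the candidate window's contribution is removed
    from the phenotype.  Includes longitudinal phenotype editing (robust
    bisquare weight cleaning, visit-error feed-intake adjustment, genotype
    quality control), a pedigree/gene-drop simulator with known ground truth,
    and variance-explained reporting with local gene-annotation intersection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    lme4,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    GenomicRanges,
    IRanges,
    rtracklayer,
    knitr,
    rmarkdown
Config/testthat/edition: 3
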