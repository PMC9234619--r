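Package: abaloneGS
Title: Genomic Selection and GWAS Pipeline for Heat Tolerance in Pacific Abalone
Version: 0.1.0
Authors@R: person("Pipeline", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested, reusable implementation of a genomic-selection analysis of
    heat-stress attachment duration in Pacific abalone (Haliotis discus hannai):
    SNP quality control and naive imputation, VanRaden genomic relationship matrix,
    principal-component population structure with Tracy-Widom significance,
    mixed-linear-model GWAS with Bonferroni and suggestive thresholds and per-SNP
    variance explained, GBLUP (eigen-rotation REML) and BayesB (Gibbs sampling)
    genomic prediction with heritability estimation, and a cross-validated
    comparison of GWAS-ranked versus random low-density SNP panels. Includes a
    synthetic-data generator emulating the study population for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    data.table,
    Rcpp,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    SummarizedExperiment,
    VariantAnnotation
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
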