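Package: ernapred
Title: Predicting Enhancer RNA Transcription from Chromatin Modifications
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to label enhancers as eRNA-transcribing or silent from
    stranded GRO-seq read densities, to learn which combinations of chromatin
    modifications predict eRNA production with a logistic regression model
    evaluated under nested cross-validation over exhaustively enumerated mark
    subsets, and to stratify enhancer activity through the expression of
    enhancer-associated genes. Includes a synthetic-data generator that
    emulates the statistical structure of ChIP-seq and GRO-seq densities at
    enhancers (bimodal log GRO-seq signal, correlated acetylation marks,
    anti-correlated repressive marks) with planted ground truth for recovery
    testing, plus readers and writers for the BED and TSV formats the
    pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    yaml,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    withr,
    testthat (>= 3.0.0),
    pROC,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
LinkingTo:
    Rcpp,
    RcppArmadillo
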