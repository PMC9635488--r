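Package: readrsa
Title: Model-Based Representational Similarity Analysis of Word Reading
Version: 0.1.0
Authors@R: person("readrsa", "developers", email = "readrsa@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing computational models of single-word reading
    against multivoxel fMRI patterns with representational similarity
    analysis (RSA). Implements a feedforward orthography-to-phonology
    network with frequency-ramped external input, a serial grapheme-phoneme
    correspondence (GPC) rule route with an optional localist lexical
    extension, slot-based binary orthographic and phonological codes,
    representational dissimilarity matrices (correlation distance) with
    rank-based plain and partial second-order comparison, spherical
    searchlight mapping over masked beta-series volumes with Gaussian
    smoothing, Fisher transformation, group t-tests and cluster-extent
    thresholding, a synthetic-data generator (artificial lexicons, nonword
    test sets, rule tables, multi-subject beta series with planted
    representational geometry), and a config-driven pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
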