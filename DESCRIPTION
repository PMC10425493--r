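Package: tempoBMT
Title: Benchmark-Time Modeling of Temporal Transcriptomics Time Courses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis of targeted bulk transcriptomics (TempO-Seq style)
    time-course experiments for time-dependent activation of cellular
    stress-response pathways. Implements per-time-point negative-binomial
    Wald differential expression with median-of-ratios normalization,
    hypergeometric over-representation analysis against gene-set
    collections, and a benchmark-time (BMT) engine that repurposes
    benchmark-dose curve fitting to the time axis: a Williams trend-test
    prefilter, ten parametric time-response models selected by AIC,
    inversion at a benchmark response, parametric-bootstrap confidence
    bounds, retention filters, accumulation curves, earliest-response
    genes, and weighted five-parameter logistic fold-change prediction.
    Includes a synthetic-data generator with planted, analytically
    characterized responders so every stage is testable against ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    MASS,
    mvtnorm,
    minpack.lm,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    multcomp
Config/testthat/edition: 3
RoxygenNote: 7.3.3
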