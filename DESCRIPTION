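Package: epiperturb
Title: Epigenome-Based Functional Profiling of Kinase Inhibitor Perturbations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Functional profiling of kinase-inhibitor perturbations from
    H3K27ac time-course count tables at cis-regulatory elements (CREs).
    Implements invariant-feature normalization via a skew-normal fit to
    between-sample log-count differences, Multiple Factor Analysis (MFA)
    across per-condition tables with permutation-based selection of
    significant dimensions, a signed perturbation-likelihood score built
    from partial-factor-score distances to the vehicle condition, inhibitor
    proximity networks and dendrograms, standardized Jaccard overlap
    statistics, permutation association between affected CREs and
    transcription-factor peak sets, and weighted multi-class prediction of
    perturbation direction with directional feature importance. Ships a
    synthetic-data generator with machine-readable ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    tools,
    methods,
    fitdistrplus,
    jsonlite,
    yaml,
    IRanges,
    GenomicRanges,
    igraph,
    xgboost,
    pROC
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
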