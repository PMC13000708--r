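Package: pgsEval
Title: Polygenic Score Evaluation Under the Liability Threshold Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for evaluating polygenic scores (PGS) in case-control
    cohorts of a rare disorder: allelic scoring of genotype dosages against
    per-variant weight tables, kinship-based relatedness pruning, greedy
    nearest-neighbour case-control matching, ancestry principal components,
    and a statistical battery covering logistic association (odds ratio per
    standard deviation of PGS), ROC discrimination with one-tailed Z
    inference on the AUC, and variance explained on the liability scale via
    the Lee ascertainment correction with bootstrap confidence intervals and
    Benjamini-Hochberg adjustment. A synthetic cohort generator under an
    additive liability-threshold model with Balding-Nichols population
    structure, correlated multi-trait effects, noisy weight estimation and
    injected related pairs makes every pipeline stage testable without
    access-controlled genotype data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    GenomicRanges,
    SummarizedExperiment,
    igraph,
    vcfR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
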