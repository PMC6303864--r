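Package: abnn
Title: Approximate Bayesian Neural Networks for Genome-Wide Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-wide prediction and SNP-effect discovery with shallow
    neural networks regularized by decoupled weight decay and Monte-Carlo
    dropout. Per-iteration Bernoulli dropout masks supply samples from an
    approximate posterior, yielding model-averaged phenotype predictions and
    posterior additive and dominance SNP effects from one-hot genotype
    encodings. Includes a quantitative-trait simulator with controlled,
    random, epistatic and dominance QTL plus a closed-form GBLUP ridge
    baseline, so the full workflow is reproducible without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    data.table,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml,
    ggplot2
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'genotype-data.R'
    'one-hot.R'
    'split.R'
    'network.R'
    'training.R'
    'posterior.R'
    'fit.R'
    'effects.R'
    'qtl-sim.R'
    'baselines.R'
    'cli.R'
    'RcppExports.R'
    'abnn-package.R'
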