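Package: deepkernGP
Title: Deep Kernel and Kernel Mixed Models for Multi-Environment Genomic Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genomic prediction of quantitative traits in multi-environment
    breeding trials with kernel mixed models. Builds the linear GBLUP genomic
    relationship matrix, the Gaussian kernel, and the recursive arc-cosine
    (deep) kernel that emulates a wide feed-forward neural network; fits
    single-environment and genotype-by-environment (G-by-E) Gaussian-process
    mixed models by maximum marginal likelihood; selects the arc-cosine layer
    count and the Gaussian bandwidth by marginal likelihood; benchmarks methods
    under sparse-testing (CV2) cross-validation with mean squared error of
    prediction; includes a compact feed-forward neural-network baseline and a
    synthetic genotype/phenotype generator for fully reproducible testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
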