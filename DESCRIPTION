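Package: ddiblock
Title: Drug-Drug Interaction Prediction with Stochastic Block Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised prediction of unknown drug-drug interaction types
    from a network of previously reported interactions. Interaction-type
    probabilities are estimated by Bayesian model averaging over stochastic
    block models, with the partition posterior sampled by a Metropolis
    algorithm; group-to-group type-probability matrices are integrated out
    analytically under a uniform Dirichlet prior. Also provides the
    comparison predictors (global-rate baseline, neighbor-based similarity,
    and the Prism II monochromaticity clustering), evaluation protocols
    (repeated random sub-sampling validation with exact and within-one-level
    accuracy, snapshot-based novel/spurious link detection with AUROC and
    sensitivity-specificity curves, and an iterative discovery simulation),
    and a synthetic-network generator with planted group structure for
    verification.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
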