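Package: eslr
Title: Evolutionary Sparse Learning for Phylogenomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Supervised sparse-group-lasso logistic regression on one-hot
    encoded multiple sequence alignments, for discovering the positions and
    genes whose variation is most concordant with a phylogenetic partition or
    a binary trait.  Provides alignment/partition/tree input handling, one-hot
    encoding with monomorphic filtering, a proximal-gradient (FISTA) solver
    for lasso, group-lasso and sparse-group-lasso penalized logistic
    regression with class balancing, cross-validation and stability selection,
    sparsity scores (BSS, PSS, GSS, FSS, HSS) and sequence prediction scores
    (SPS, SPP) with ROC/AUC, bootstrap and permutation significance machinery,
    and a synthetic-alignment simulator with planted clade-diagnostic signal.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    jsonlite,
    phangorn,
    stats,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
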