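Package: nglyc
Title: N-Linked Glycosylation Site Prediction from Position-Relative
    Features and Statistical Moments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts N-linked glycosylation sites in protein sequences
    from fixed-length site vicinity windows centred on asparagine.
    Windows are summarised by a position- and composition-variant
    feature set: the integer-encoded site vicinity vector, residue
    frequency and accumulative position-incidence vectors (forward and
    reverse), position-relative incidence matrices (PRIM/RPRIM), and
    raw, central and discrete Hahn moments of the window grid and both
    incidence matrices.  A multilayer feed-forward network trained by
    full-batch back-propagation with an adaptive learning rate scores
    candidate sites.  Includes self-consistency, stratified k-fold
    cross-validation and jackknife evaluation with sensitivity,
    specificity, accuracy, Matthews correlation and ROC/AUC, plus a
    seeded generator of sequon-biased synthetic windows for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
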