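Package: rifsignature
Title: Endometrial Expression Signature Discovery for Recurrent Implantation Failure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of a two-channel microarray analysis
    pipeline for discovering and evaluating an endometrial gene expression
    signature of recurrent implantation failure (RIF). Covers quantile
    normalization, dye-swap merging, probe filtering, per-gene linear-model
    correction of batch and biopsy-timing effects, resampling-based
    signal-to-noise feature selection with a probability-calibrated linear
    support vector machine, Wilson-interval diagnostic metrics with ROC/AUC,
    parametric gene-set enrichment (Z-scores on per-gene t statistics), and
    per-patient classification-error-rate stratification. Ships a synthetic
    data generator with planted class, batch, timing, and enrichment
    structure so the full pipeline is testable without any data download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    limma,
    pROC,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
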