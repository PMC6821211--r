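Package: cvsig
Title: Cell Viability Signatures from Perturbation Transcriptomics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Links landmark-gene perturbation transcriptomics signatures to
    cell viability screens. Provides moderated z-score (MODZ) consensus
    signatures, dose-tolerant matching of signatures to viability records,
    ridge regression cell viability signature (CVS) models with within- and
    across-screen validation, gene-level viability statistics and permutation
    set scoring, de-confounded mechanism-of-action similarity analysis,
    screen-wide toxicity classification, baseline-expression association
    analyses (drug sensitivity, general level of drug sensitivity, partial
    correlations), and random-forest drug sensitivity models with consensus
    signature drug features. Includes a fully specified synthetic-data
    generator with planted ground truth so every stage is testable without
    external screen downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    mclust,
    ranger
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
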