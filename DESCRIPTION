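Package: siamdr
Title: Contrastive Representation Learning for Cancer Drug Response Prioritization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Ranks candidate drugs for cancer cell lines from secondary-screen
    dose-response data. Provides a composite continuous effective score built
    from AUC, curve lower limit and IC50 with top-decile binarization; a
    record-filtering cascade for screen quality and duplicate resolution;
    Siamese (twin-network) contrastive pretraining of drug and cell-line
    encoders that preserves gene-target and cancer-type group structure, with
    a reconstruction-autoencoder baseline embedder; logistic, random-forest
    and feed-forward end classifiers over concatenated drug-cell features;
    precision-at-k ranking evaluation at cell and cancer level; embedding
    cohesion and separability diagnostics; cancer-stratified splits with a
    novel-cancer holdout; and a synthetic-data generator that plants
    mechanism-of-action and cancer-type group structure so the whole pipeline
    is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    jsonlite,
    ranger,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
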