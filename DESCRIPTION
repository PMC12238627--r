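Package: concretr
Title: Automated Concreteness Ratings from Dual Text Embeddings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts lexical concreteness (1-5 Likert scale) for words,
    multi-word expressions and sentences from a dual text-embedding
    representation: a 512-dimensional base embedding concatenated with a
    512-dimensional emotion-aware embedding, fed to a small feed-forward
    regressor trained on human concreteness norms. Includes corpus loaders
    and stratified splitting for norm datasets, a routing prediction
    pipeline with language detection and translation adapters for
    cross-lingual input, contrastive fine-tuning of a paired image-text
    encoder, evaluation metrics (Pearson r, R-squared, MAE, RMSE),
    inter-rater reliability estimation (Spearman-Brown corrected split-half
    reliability and intraclass correlation), and synthetic-data generators
    with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    lme4,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
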