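Package: fewshotSNN
Title: Few-Shot Sentence Classification with Siamese Neural Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Few-shot (N-way-K-shot) text classification over sentence
    embeddings using Siamese-network-style methods. Implements the
    pretrained-embedding classifier (PT-SNN): vectorized mean per-class
    cosine-similarity classification over frozen sentence embeddings; the
    second-order-embedding variant (SOE-SNN): a weight-sharing bidirectional
    LSTM encoder stacked on frozen embeddings and trained with contrastive
    binary cross-entropy on exhaustive same/different-class sample pairs;
    exhaustive pair augmentation; seeded episodic evaluation with
    M-iteration metric averaging; a prefix-prompt builder for generative
    baselines; and a synthetic class-conditional embedding generator so the
    whole pipeline is testable offline without access to restricted clinical
    corpora.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    withr,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'embeddings.R'
    'pairs.R'
    'ptsnn.R'
    'soe.R'
    'evaluation.R'
    'prompt.R'
    'synthetic.R'
    'io.R'
    'experiment.R'
    'fewshotSNN-package.R'
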