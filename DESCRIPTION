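Package: weakner
Title: Ontology-Driven Weak Supervision for Medical Entity Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds word-level entity classifiers for biomedical and clinical
    text without hand-labeled training data. Terminologies (flat term lists
    with semantic-type assignments) are turned into labeling functions via
    reusable templates: longest-match semantic-type tagging, document-scoped
    synonym-set disambiguation with Schwartz-Hearst abbreviation linking,
    context-window cue rules, and pattern rules. The resulting label matrix
    is denoised by a data-programming label model that estimates each
    source's latent accuracy from pairwise agreement rates via the triplet
    method, yielding probabilistic token labels. A discriminative sequence
    classifier is then trained on those soft labels with a noise-aware
    expected cross-entropy loss, masking tokens on which every source
    abstained, so that it generalizes beyond dictionary coverage. Includes
    exact-span and token-level evaluation, seeded synthetic corpus and
    label-source generators for benchmarking, and an end-to-end pipeline
    runner.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
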