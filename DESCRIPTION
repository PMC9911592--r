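Package: alextract
Title: Active Learning for Clinical Information Extraction with
    Pseudo-Perplexity Sampling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building named-entity and relation annotations over
    clinical free-text reports with an active-learning workflow. Provides a
    general radiology annotation schema (20 entity classes, 15 relation
    classes), reading and writing of brat standoff corpora, section and
    sentence segmentation, IOB sequence encoding and within-sentence
    relation-pair sample generation with positive oversampling, intrinsic
    pseudo-perplexity scoring of unlabeled sentences under a masked language
    model, strategic percentile-band batch selection, the full
    annotate-train-query loop with soft labels and an oracle annotator for
    simulation, strict-span macro-F1 evaluation and corpus diagnostics, and a
    synthetic pseudo-clinical corpus generator so every stage is testable
    without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    tibble,
    tidyr,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
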