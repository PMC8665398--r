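Package: graphsts
Title: Knowledge-Graph-Augmented Clinical Semantic Textual Similarity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Scores pairs of clinical sentences for semantic similarity on
    the 0-5 rubric used by clinical STS benchmarks, fusing a trainable text
    encoder with a graph convolutional encoder of per-sentence concept
    subgraphs induced from a SNOMED CT-style terminology graph. Includes
    readers for RRF-dialect concept and relation files, a dictionary concept
    tagger, concept-based data augmentation, knowledge-graph-embedding node
    initialization, teacher-bounded knowledge distillation, ensembling,
    Pearson-based evaluation with per-category breakdowns, and a synthetic
    benchmark generator with a planted graph-proximity signal.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
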