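Package: tcmnorm
Title: Fine-Grained Annotation, Rule-Based Relation Extraction and
    Normalization of TCM Symptom Narratives
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A toolkit for fine-grained symptom information processing in
    Chinese present-illness narratives from traditional Chinese medicine
    (TCM) electronic medical records. Provides a typed annotation data
    model (12 entity types, 10 directed relation types with a fixed
    endpoint-constraint matrix), readers and writers for relation-style
    annotation JSONL, five deterministic rule-based relation-extraction
    procedures driven by clause and sentence segmentation on the
    full-width comma and period, combination rules that normalize
    entity-relation graphs into standardized symptom rows, strict
    span-level precision/recall/F1 scoring including pairwise
    inter-annotator agreement and a per-sentence annotation-rate metric,
    a longest-match dictionary tagger, and a seeded synthetic-corpus
    generator with construction-derived gold relations for end-to-end
    testing without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
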