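Package: raremine
Title: Ontology-Enhanced Extraction of Rare-Disease Entities, Relations and
    Knowledge Graphs from Medical Text
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for mining rare-disease information from
    unstructured medical text with an ontology-enhanced large language model.
    Compiles rare-disease, disease and phenotype lexicons plus
    (rare disease, frequency, phenotype) association triples from OBO or
    tabular ontology sources; segments documents at paragraph boundaries
    under a token budget; performs staged entity extraction (dictionary
    string matching with negation detection, term expansion, typed entity
    extraction), relation extraction with injected ontology knowledge, and
    entity calibration; resolves anaphora and builds a deduplicated typed
    knowledge graph exportable to GraphML, CSV node/edge lists or Cypher.
    Includes a BRAT standoff corpus reader, a deterministic fixture-driven
    mock language-model backend with configurable corruption so the whole
    pipeline is testable offline, a synthetic ontology and corpus generator,
    and an evaluation harness computing per-type and overall precision,
    recall and F1 together with error-augmented confusion matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
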