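Package: funcoh
Title: Functional Coherence of Protein Sets from Gene Ontology
    Annotations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies how functionally coherent a set of proteins is,
    given their Gene Ontology annotations. Implements the naive annotation
    agreement score, the groupwise semantic similarity metrics simUI and
    simGIC over ancestor-extended annotation sets, and the hybrid metrics
    mUI and mGIC, which restrict similarity to the terms found
    over-represented by a Fisher exact test with topology-based (Elim)
    elimination, thereby isolating the functional core of a protein
    family. Includes a random-replacement degeneration assay for
    benchmarking the noise resilience and resolution of any such metric,
    generators for synthetic ontologies and annotation corpora, parsers
    and writers for OBO and GAF 2.x, and Graphviz DOT export of
    annotation-flow graphs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    stats,
    utils,
    withr
Suggests:
    ggplot2,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
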