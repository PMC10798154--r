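Package: sbmlgraph
Title: Schema-Driven Import of SBML Models into Labeled Property Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts Systems Biology Markup Language (SBML) documents into
    labeled property graphs driven by a user-drawn graph schema in the Arrows
    export format. A name-matching engine resolves which components, attributes
    and inter-component relationships to extract, producing an in-memory
    property graph with merge-by-key semantics and a per-import tag. Graphs can
    be emitted as idempotent parameterized Cypher for Neo4j, exported to JSON or
    GraphML, and analyzed with metabolic-network operations: species
    neighborhoods, dense-node flagging, fixed-length producer paths,
    species-reference contraction and degree-based pruning. Includes a
    deterministic synthetic-SBML generator and an independent XML reference-scan
    oracle for verification without a database.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    tibble,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
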