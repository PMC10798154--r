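# sbmlgraph

Schema-driven import of SBML models into labeled property graphs, in R.

## The problem

Genome-scale metabolic models (GEMs) and other reaction-based models are
exchanged as SBML — an XML format whose components (species, reactions,
compartments, parameters, gene products, ...) form a deeply nested tree
laced with cross-references. Graph databases such as Neo4j are a natural
home for this data: entities become nodes, their references become typed
edges, and Cypher traversals replace ad-hoc XML walking. The difficulty is
deciding *what* to extract: a fixed importer either dumps everything or
hard-codes one application's slice of the standard.

`sbmlgraph` instead lets the analyst *draw* the slice. A small graph schema
(drawn in the Arrows web app and exported as JSON) names the SBML components
to keep — node labels match component names, node properties match
attribute names — and the typed, directed relationships to materialize
between them. A name-matching engine then resolves each drawn relationship
against the document by three strategies, tried most-specific first:

1. **target-name** — the source component stores the target's identifier in
   an attribute named after the target (`Species.compartment` →
   `Compartment`);
2. **relationship-name** — an attribute or `listOf*` container named after
   the relationship type (verb prefixes `HAS`/`IS`/`IN` stripped) supplies
   the target ids (`HAS_UNITS` → `units`; `HAS_PRODUCT` →
   `listOfProducts`);
3. **containment** — the target is nested beneath the source, or referenced
   by id from a nested element (`Reaction` → `GeneProduct` through
   `geneProductRef`).

The result is an in-memory labeled property graph with merge-by-key
semantics — the key being (primary label, component id or a deterministic
surrogate, import tag), so several model versions can coexist in one store
without cross-linking. The graph can be emitted as idempotent,
parameterized Cypher (`MERGE` on `{id, tag}`, batched `UNWIND` payloads),
exported to JSON or GraphML, or analyzed directly: species neighborhoods,
dense-node flagging, fixed-length producer paths, species-reference
contraction and degree-based pruning.

Everything is verifiable without a database: a bundled in-memory Cypher
MERGE interpreter replays emitted scripts, and an independent XML
reference-scan oracle recomputes every node and edge count from the raw
document.

## Worked example

```r
library(sbmlgraph)

# a two-species / one-reaction micro-model, generated deterministically
xml <- generate_model(fixture_spec(n_compartments = 1, n_species = 2,
                                   n_reactions = 1))

# the bundled metabolite/reaction/compartment schema
g <- map_document(xml, example_schema("metabolic"), tag = "demo")
graph_stats(g)
#> # A tibble: 6 × 3
#>   element      name               n
#>   <chr>        <chr>          <int>
#> 1 node         Compartment        1
#> 2 node         Reaction           1
#> 3 node         Species            2
#> 4 relationship HAS_PRODUCT        1
#> 5 relationship IN_COMPARTMENT     2
#> 6 relationship IS_REACTANT        1
```

Both species link to their compartment by the target-name strategy; the
reaction links to its reactant and product through its `listOfReactants` /
`listOfProducts` containers by the relationship-name strategy:

```r
resolution_trace(g)[, c("type", "strategy", "n_edges")]
#> # A tibble: 3 × 3
#>   type           strategy          n_edges
#>   <chr>          <chr>               <int>
#> 1 IN_COMPARTMENT target-name             2
#> 2 HAS_PRODUCT    relationship-name       1
#> 3 IS_REACTANT    relationship-name       1
```

Emitting Cypher (data travels only in the parameter payloads):

```r
to_cypher(g)$statement[1]
#> UNWIND $rows AS row MERGE (n:`Species` {id: row.id, tag: row.tag}) SET n += row.props
```

`load_graph(g, import_config(dry_run = "out.cypher"))` writes the script
plus a JSON-lines parameter sidecar; with a live Neo4j connection you plug
a driver call in as the `executor`. The same pipeline is available from a
shell through `inst/scripts/sbmlgraph` (`import`, `stats`, `export`, `ops`
subcommands).

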