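---
title: "Schema-driven import of SBML models into property graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Schema-driven import of SBML models into property graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sbmlgraph)
```

## The model behind the package

SBML documents describe reaction networks as a tree of *components* —
species, reactions, compartments, parameters, unit definitions, and (in
Level 3 packages) gene products, groups, layouts and qualitative species.
Components refer to each other by storing identifiers in attributes, by
grouping references inside `listOf*` containers, and by plain nesting.
`sbmlgraph` converts a selected part of this tree into a labeled property
graph. The selection is itself a small graph — an Arrows-export JSON
document — whose node labels name SBML component kinds, whose node
properties name attributes, and whose typed, directed relationships name
the links to materialize.

Two conventions carry the whole mechanism:

* **Name matching is canonical.** Labels, properties and types are compared
  case- and punctuation-insensitively (`normalize_name()`), so
  `UnitDefinition` in a schema matches the `unitDefinition` element. For
  relationship types, leading verb tokens `HAS`, `IS`, `IN` are stripped
  and a trailing plural `s` is ignored, so `HAS_UNITS` matches the `units`
  attribute and `HAS_PRODUCT` the `listOfProducts` container. We chose
  case-insensitive matching deliberately: it is strictly more permissive
  than exact matching, reproduces every documented label/attribute pairing
  without a lookup table, and cannot silently drop data (an unmatched name
  yields a diagnostic, not an error).

* **Relationship resolution is ordered most-specific-first.** For each
  source instance the three strategies — target-name, relationship-name,
  containment — are tried in that fixed order and the first non-empty
  result wins. The order matters: containment is the least specific
  strategy and would otherwise shadow precise attribute references (a
  reaction *contains* species references to every participant, but its
  `listOfProducts` names exactly the products). Restricting containment's
  referential phase to *descendants of the source* also prevents the
  over-linking failure mode where a layout connects to every dimensions
  record in the document rather than its own; reference implementations of
  this idea are known to differ on that input class, and we deliberately
  chose the contained-only reading.

Every imported node carries an import **tag** in its merge key
(primary label, component id, tag). Components without ids — Level 2
species references, event assignments — get a deterministic surrogate
derived from their document path with `listOf*` wrappers elided
(`event[0]/eventAssignment[0]`), so re-imports merge instead of
duplicating, and two sequentially imported model versions can never
cross-link.

## Parameters that matter

| Parameter | Where | Default | Why |
|---|---|---|---|
| `tag` | `map_document()` | model `id`, else file stem | disambiguates multi-model stores; part of every merge key |
| `batch_size` | `to_cypher()` | 1000 rows | standard bulk-load batch; statement text is independent of the data, so any batch size yields the same store |
| `radius` | `species_neighborhood()` | 1 hop | the "metabolite and its reactions" view; monotone in `radius` |
| `threshold` | `flag_dense_nodes()` | — | degree at or above which a node is flagged `dense`; used to exclude hub (currency) metabolites |
| `n_reactions` | `producers_at_distance()` | 2 | exact number of reaction steps on a producer path |
| `min_reactions` | `prune_species_by_degree()` | — | species under this many *distinct* adjacent reactions are removed, one pass, no cascade |

Pruning counts distinct Reaction neighbors, not edge multiplicity: a
species participating twice in one reaction is still connected to one
reaction, which is the biologically meaningful notion of connectivity
here. Pruning runs a single pass by design — a cascade would make the
result depend on removal order and delete well-connected species whose
neighbors happened to go first.

## Path semantics

`producers_at_distance()` enumerates *simple* (node-disjoint) paths that
end at the target species and traverse exactly `n_reactions` reaction
nodes, starting from species in a named compartment. Traversal follows
biochemistry rather than stored arrow direction: a species enters
reactions it is a *reactant* of and leaves through their *products*. With
the bundled schemas those facts are stored as `IS_REACTANT` and
`HAS_PRODUCT` edges drawn from the Reaction node (that orientation is what
the name-matching engine can resolve, since the reaction's `listOf*`
containers hold the references), so the operation interprets edge
orientation per type; `reactant_types`/`product_types` arguments
accommodate schemas drawn with other names. Node-disjointness excludes
circular dependencies by construction. The implementation delegates to
igraph's simple-path enumeration; tests compare it against an independent
recursive DFS on graphs of up to ~100 nodes.

## Numerical and formatting choices

* **Attribute typing.** SBML attribute values stay strings except those the
  specification declares numeric (`stoichiometry`, `size`, `value`, ...) or
  boolean (`constant`, `reversible`, ...), which are coerced. An
  unparseable declared-numeric value is kept as a string with a warning:
  imports of sloppy models must not fail.
* **Mathematical expressions** are serialized from MathML to a fixed infix
  dialect — single spaces around binary operators, nested infix operands
  parenthesized, functions as `f(x, y)` — so `math` properties are
  reproducible strings. Annotations and notes are stored as raw XML text,
  unparsed.
* **Merge conflicts.** When an upsert rewrites an existing property, the
  incoming value wins and a condition is signalled. This mirrors
  `MERGE ... SET` in Cypher, so the in-memory graph and a database load
  agree by construction.
* **Dangling references** (an attribute naming a non-existent id) drop the
  edge with a warning, never an error: models in the wild contain them,
  and an importer's job is faithful extraction of what is resolvable.
* **Duplicate participation** (a species listed twice as reactant) collapses
  to one edge: edge identity is (type, source key, target key).

## What the synthetic generator emulates — and what it does not

`generate_model()` produces SBML L3V2 documents with compartments, species
assigned round-robin, reactions whose participants are drawn from a
private seeded linear-congruential stream (byte-identical output per
spec), and optional fbc (flux-bound parameters, gene products with
`geneProductRef` associations), groups, layout and qual layers. The
default spec — one compartment, two species, one reaction — is the
canonical micro-model used across the documentation and tests. Products
avoid the drawing reaction's own reactants when possible, since a
self-conversion is not a meaningful reaction.

The generator covers the structural features the mapper exercises:
id-bearing and id-less components, package-qualified attributes, nested
references, `listOf*` containers. It does **not** reproduce the content of
real genome-scale models: no annotation/CV-term payloads, no realistic
stoichiometry or reversibility distributions, no multi-thousand-node
scale, no malformed-in-the-wild quirks beyond those tests inject
explicitly. Passing tests therefore demonstrate correctness of the
extraction and analysis machinery on well-formed structure, not
performance or robustness claims at GEM scale; full-scale reproduction
requires downloading published GEMs and is intentionally outside the test
suite. Test problem sizes — fixture sweeps of twenty seeded models of
roughly 5–10 species crossed with three schemas, path-oracle graphs of
~30 nodes — were chosen as the smallest sizes that exercise every code
path several times over.

## The verification design

Two independent routes answer every counting question. The mapper walks a
parsed component-record tree; the oracle (`ground_truth()`) re-derives
label and relationship counts by scanning the raw XML with the same
strategy precedence but none of the mapper's machinery. Their exact
agreement over seeded fixture sweeps is the package's central acceptance
property. Likewise, Cypher emission is verified by a minimal in-memory
MERGE interpreter that understands exactly the emitted statement shapes:
replaying a script twice must leave the store unchanged, and the store's
statistics must equal the source graph's. The interpreter doubles as the
default `executor` for `load_graph()`, which keeps the load contract
(transactional batches, fail-fast with the failed batch index) testable
without a server; a live Neo4j deployment supplies its own executor
wrapping a driver call.

## Known limitations

* Annotations are carried as raw XML; RDF/CV terms are not parsed into
  structured properties.
* Schema relationship properties are read from the *source* component's
  attributes; there is no syntax for deriving edge properties from the
  reference element itself (e.g. stoichiometry on a participation edge
  extracted directly from the species reference — model SpeciesReference
  as a node and contract it later if that is needed).
* Whether a reference tool would create one edge per repeated reference is
  unknowable from its outputs alone; we collapse duplicates and document
  it.
* No SBML validation beyond well-formedness and id-uniqueness warnings; no
  unit checking; no simulation.

```{r example}
xml <- generate_model(fixture_spec())
g <- map_document(xml, example_schema("metabolic"), tag = "demo")
graph_stats(g)
resolution_trace(g)[, c("type", "strategy", "n_edges")]
```
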