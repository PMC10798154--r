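# Shared fixtures, all built in code at test time.

toy1_xml <- function() generate_model(fixture_spec())

metabolic_schema <- function() load_schema(example_schema("metabolic"))
gem_schema <- function() load_schema(example_schema("gem"))

# Build an Arrows export JSON string from compact node/relationship specs.
arrows_json <- function(nodes, relationships = list()) {
  nds <- purrr::imap(nodes, function(nd, i) {
    list(id = nd$id %||% paste0("n", i - 1L),
         position = list(x = 0, y = 0), caption = "",
         labels = as.list(nd$labels),
         properties = nd$properties %||% stats::setNames(list(), character()),
         style = stats::setNames(list(), character()))
  })
  rls <- purrr::imap(relationships, function(rl, i) {
    list(id = paste0("r", i - 1L), type = rl$type,
         fromId = rl$from, toId = rl$to,
         properties = rl$properties %||% stats::setNames(list(), character()))
  })
  as.character(jsonlite::toJSON(list(nodes = nds, relationships = rls),
                                auto_unbox = TRUE))
}

# Model/Species/Reaction schema resolved purely by containment + listOf names;
# third schema of the oracle-equivalence sweep.
membership_schema <- function() {
  load_schema(arrows_json(
    nodes = list(
      list(id = "n0", labels = "Model",
           properties = list(id = "string", name = "string")),
      list(id = "n1", labels = "Species", properties = list(id = "string")),
      list(id = "n2", labels = "Reaction", properties = list(id = "string"))
    ),
    relationships = list(
      list(type = "HAS_SPECIES", from = "n0", to = "n1"),
      list(type = "HAS_REACTION", from = "n0", to = "n2"),
      list(type = "IS_REACTANT", from = "n2", to = "n1")
    )))
}

# Hand-written L3 micro-model with a unitDefinition, a kineticLaw holding a
# localParameter (with units), and an id-less event/eventAssignment pair.
kinetic_xml <- function() {
  paste0('<?xml version="1.0" encoding="UTF-8"?>\n',
'<sbml xmlns="http://www.sbml.org/sbml/level3/version2/core" level="3" version="2">\n',
'  <model id="kin1">\n',
'    <listOfUnitDefinitions><unitDefinition id="u1"/></listOfUnitDefinitions>\n',
'    <listOfCompartments><compartment id="c" size="1" constant="true"/></listOfCompartments>\n',
'    <listOfSpecies>\n',
'      <species id="A" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>\n',
'      <species id="B" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>\n',
'    </listOfSpecies>\n',
'    <listOfReactions>\n',
'      <reaction id="R1" reversible="false">\n',
'        <listOfReactants><speciesReference species="A" stoichiometry="1" constant="true"/></listOfReactants>\n',
'        <listOfProducts><speciesReference species="B" stoichiometry="1" constant="true"/></listOfProducts>\n',
'        <kineticLaw>\n',
'          <math xmlns="http://www.w3.org/1998/Math/MathML">\n',
'            <apply><times/><ci>k1</ci><ci>A</ci></apply>\n',
'          </math>\n',
'          <listOfLocalParameters>\n',
'            <localParameter id="k1" value="0.5" units="u1"/>\n',
'          </listOfLocalParameters>\n',
'        </kineticLaw>\n',
'      </reaction>\n',
'    </listOfReactions>\n',
'    <listOfEvents>\n',
'      <event useValuesFromTriggerTime="true">\n',
'        <listOfEventAssignments><eventAssignment variable="A"/></listOfEventAssignments>\n',
'      </event>\n',
'    </listOfEvents>\n',
'  </model>\n',
'</sbml>')
}

# Star-shaped synthetic model: one hub species ("fumarate"-like) that is a
# reactant of n_rx reactions, each producing its own peripheral species.
hub_model_xml <- function(n_rx, model_id = "hubmodel") {
  L <- c('<?xml version="1.0" encoding="UTF-8"?>',
         paste0('<sbml xmlns="http://www.sbml.org/sbml/level3/version2/core"',
                ' level="3" version="2">'),
         paste0('  <model id="', model_id, '">'),
         '    <listOfCompartments>',
         '      <compartment id="c" size="1" constant="true"/>',
         '    </listOfCompartments>',
         '    <listOfSpecies>',
         paste0('      <species id="hub" name="fumarate" compartment="c"',
                ' hasOnlySubstanceUnits="false" boundaryCondition="false"',
                ' constant="false"/>'))
  for (i in seq_len(n_rx)) {
    L <- c(L, paste0('      <species id="P', i, '" name="peripheral ', i,
                     '" compartment="c" hasOnlySubstanceUnits="false"',
                     ' boundaryCondition="false" constant="false"/>'))
  }
  L <- c(L, '    </listOfSpecies>', '    <listOfReactions>')
  for (i in seq_len(n_rx)) {
    L <- c(L,
      paste0('      <reaction id="RX', i, '" name="reaction ', i,
             '" reversible="false">'),
      '        <listOfReactants>',
      '          <speciesReference species="hub" stoichiometry="1" constant="true"/>',
      '        </listOfReactants>',
      '        <listOfProducts>',
      paste0('          <speciesReference species="P', i,
             '" stoichiometry="1" constant="true"/>'),
      '        </listOfProducts>',
      '      </reaction>')
  }
  paste(c(L, '    </listOfReactions>', '  </model>', '</sbml>'),
        collapse = "\n")
}

# Linear chain A -> R1 -> B -> R2 -> C ... as a property graph, species in
# compartment "c" by property; edges stored schema-style from the Reaction.
chain_graph <- function(n_species = 3L, tag = "chain") {
  g <- property_graph()
  sp <- sprintf("S%d", seq_len(n_species))
  for (s in sp) {
    g <- upsert_node(g, list(label = "Species", id = s, tag = tag,
                             properties = list(name = s, compartment = "c")))
  }
  for (i in seq_len(n_species - 1L)) {
    rid <- sprintf("R%d", i)
    g <- upsert_node(g, list(label = "Reaction", id = rid, tag = tag))
    g <- upsert_relationship(g, list(
      type = "IS_REACTANT", source = find_nodes(g, "Reaction", rid),
      target = find_nodes(g, "Species", sp[[i]])))
    g <- upsert_relationship(g, list(
      type = "HAS_PRODUCT", source = find_nodes(g, "Reaction", rid),
      target = find_nodes(g, "Species", sp[[i + 1L]])))
  }
  g
}

# Random bipartite species/reaction graph for path-oracle comparisons.
random_metabolic_graph <- function(n_species, n_reactions, seed,
                                   tag = "rand") {
  withr::with_seed(seed, {
    g <- property_graph()
    sp <- sprintf("S%d", seq_len(n_species))
    comps <- c("c", "e")
    for (i in seq_along(sp)) {
      g <- upsert_node(g, list(
        label = "Species", id = sp[[i]], tag = tag,
        properties = list(name = sp[[i]],
                          compartment = sample(comps, 1))))
    }
    for (i in seq_len(n_reactions)) {
      rid <- sprintf("R%d", i)
      g <- upsert_node(g, list(label = "Reaction", id = rid, tag = tag))
      rkey <- find_nodes(g, "Reaction", rid)
      reactants <- sample(sp, sample(1:2, 1))
      products <- sample(setdiff(sp, reactants), sample(1:2, 1))
      for (s in reactants) {
        g <- upsert_relationship(g, list(type = "IS_REACTANT", source = rkey,
                                         target = find_nodes(g, "Species", s)))
      }
      for (s in products) {
        g <- upsert_relationship(g, list(type = "HAS_PRODUCT", source = rkey,
                                         target = find_nodes(g, "Species", s)))
      }
    }
    g
  })
}

# Exhaustive DFS oracle for producers_at_distance: enumerates node-disjoint
# species->reaction->...->target walks of exactly n reactions, independent of
# the igraph-based implementation.
dfs_producer_paths <- function(graph, target_name, compartment, n_reactions) {
  nodes <- graph$nodes
  labels <- stats::setNames(nodes$label, nodes$key)
  prop <- function(k, nm) nodes$properties[[match(k, nodes$key)]][[nm]]
  rel <- graph$relationships
  reactions_of <- function(sp_key) {   # reactions sp is a reactant of
    unique(c(rel$source[rel$type == "IS_REACTANT" & rel$target == sp_key],
             rel$target[rel$type == "IS_REACTANT" & rel$source == sp_key]))
  }
  products_of <- function(r_key) {
    unique(c(rel$target[rel$type == "HAS_PRODUCT" & rel$source == r_key],
             rel$source[rel$type == "HAS_PRODUCT" & rel$target == r_key]))
  }
  targets <- nodes$key[nodes$label == "Species" &
                       purrr::map_lgl(nodes$properties, function(p)
                         identical(p$name %||% p$id, target_name))]
  sources <- nodes$key[nodes$label == "Species" &
                       purrr::map_lgl(nodes$properties, function(p)
                         identical(p$compartment, compartment))]
  sources <- setdiff(sources, targets)
  found <- list()
  recurse <- function(path, sp_key, steps_left) {
    if (steps_left == 0L) {
      if (sp_key %in% targets) found[[length(found) + 1L]] <<- path
      return(invisible(NULL))
    }
    for (r in setdiff(reactions_of(sp_key), path)) {
      for (p in setdiff(products_of(r), path)) {
        recurse(c(path, r, p), p, steps_left - 1L)
      }
    }
  }
  for (s in sources) recurse(s, s, n_reactions)
  found
}

# stats-table equality with zero-count rows treated as absent
expect_stats_equal <- function(mapped, oracle) {
  j <- dplyr::full_join(mapped, oracle, by = c("element", "name"),
                        suffix = c(".m", ".o"))
  j$n.m[is.na(j$n.m)] <- 0L
  j$n.o[is.na(j$n.o)] <- 0L
  expect_equal(j$n.m, j$n.o,
               info = paste(utils::capture.output(print(j)), collapse = "\n"))
}
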