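test_that("surrogate keys follow the listOf-eliding path dialect", {
  doc <- parse_document(kinetic_xml())
  ev_assign <- records_of_kind(doc, "eventAssignment")[[1]]
  expect_equal(surrogate_key(ev_assign), "event[0]/eventAssignment[0]")
  refs <- records_of_kind(doc, "speciesReference")
  keys <- purrr::map_chr(refs, surrogate_key)
  expect_equal(length(unique(keys)), length(keys))
  # stable across re-parses
  again <- purrr::map_chr(
    records_of_kind(parse_document(kinetic_xml()), "speciesReference"),
    surrogate_key)
  expect_identical(keys, again)
})

test_that("extract_nodes produces one node per selected instance", {
  doc <- parse_document(toy1_xml())
  nodes <- extract_nodes(doc, metabolic_schema(), tag = "t")
  expect_equal(nrow(nodes), 4L)  # 2 species + 1 reaction + 1 compartment
  expect_setequal(unique(nodes$label),
                  c("Species", "Reaction", "Compartment"))
  # every node property map carries the tag and id
  for (p in nodes$properties) {
    expect_equal(p$tag, "t")
    expect_true(nzchar(p$id))
  }
  # node-count invariant against the catalog
  cat <- component_catalog(doc)
  for (lab in unique(nodes$label)) {
    expect_equal(sum(nodes$label == lab),
                 sum(cat$n[cat$kind_norm == normalize_name(lab)]))
  }
  empty <- load_schema('{"nodes": [], "relationships": []}')
  expect_equal(nrow(extract_nodes(doc, empty, tag = "t")), 0L)
})

test_that("target-name strategy resolves species to compartment", {
  doc <- parse_document(kinetic_xml())
  sp <- records_of_kind(doc, "species")[[1]]
  expect_equal(resolve_by_target_name(sp, "Compartment", doc), "c")
  rx <- records_of_kind(doc, "reaction")[[1]]
  expect_equal(resolve_by_target_name(rx, "Compartment", doc), character())
})

test_that("dangling target-name references warn and resolve to nothing", {
  xml <- sub('compartment="c"', 'compartment="zz"', kinetic_xml())
  doc <- parse_document(xml)
  sp <- records_of_kind(doc, "species")[[1]]
  expect_warning(out <- resolve_by_target_name(sp, "Compartment", doc),
                 class = "sbmlgraph_dangling_reference")
  expect_equal(out, character())
})

test_that("relationship-name strategy covers scalar and listOf cases", {
  doc <- parse_document(kinetic_xml())
  lp <- records_of_kind(doc, "localParameter")[[1]]
  expect_equal(
    resolve_by_relationship_name(lp, "HAS_UNITS", "UnitDefinition", doc),
    "u1")
  rx <- records_of_kind(doc, "reaction")[[1]]
  expect_equal(
    resolve_by_relationship_name(rx, "HAS_PRODUCT", "Species", doc), "B")
  expect_equal(
    resolve_by_relationship_name(rx, "IS_REACTANT", "Species", doc), "A")
  expect_equal(
    resolve_by_relationship_name(rx, "HAS_NOTHING", "Species", doc),
    character())
})

test_that("containment strategy finds nested then referenced targets", {
  doc <- parse_document(kinetic_xml())
  rx <- records_of_kind(doc, "reaction")[[1]]
  expect_equal(resolve_by_containment(rx, "LocalParameter", doc), "k1")
  lp <- records_of_kind(doc, "localParameter")[[1]]
  expect_equal(resolve_by_containment(lp, "Species", doc), character())
  # phase 2: Reaction -> GeneProduct through nested geneProductRef
  fbc <- parse_document(generate_model(fixture_spec(packages = "fbc")))
  rx2 <- records_of_kind(fbc, "reaction")[[1]]
  expect_equal(resolve_by_containment(rx2, "GeneProduct", fbc), "G1")
})

test_that("map_document on the toy model reproduces the reference counts", {
  g <- map_document(toy1_xml(), metabolic_schema(), tag = "toy1")
  s <- graph_stats(g)
  lk <- function(el, nm) s$n[s$element == el & s$name == nm]
  expect_equal(lk("node", "Species"), 2L)
  expect_equal(lk("node", "Reaction"), 1L)
  expect_equal(lk("node", "Compartment"), 1L)
  expect_equal(lk("relationship", "IN_COMPARTMENT"), 2L)
  expect_equal(lk("relationship", "HAS_PRODUCT"), 1L)
  expect_equal(lk("relationship", "IS_REACTANT"), 1L)
  expect_equal(nrow(g$nodes), 4L)
  expect_equal(nrow(g$relationships), 4L)
})

test_that("edges follow the schema's drawn direction", {
  g <- map_document(toy1_xml(), metabolic_schema(), tag = "t")
  rels <- tidy(g, "relationships")
  drawn <- tibble::tribble(
    ~type, ~source_label, ~target_label,
    "IN_COMPARTMENT", "Species", "Compartment",
    "HAS_PRODUCT", "Reaction", "Species",
    "IS_REACTANT", "Reaction", "Species")
  for (i in seq_len(nrow(rels))) {
    want <- drawn[drawn$type == rels$type[[i]], ]
    expect_equal(rels$source_label[[i]], want$source_label)
    expect_equal(rels$target_label[[i]], want$target_label)
  }
})

test_that("relationships with endpoints missing from the schema error", {
  sch <- metabolic_schema()
  rel <- as.list(sch$relationships[1, ])
  rel$source_key <- "ghost"
  doc <- parse_document(toy1_xml())
  nodes <- extract_nodes(doc, sch, "t")
  expect_error(resolve_relationship(rel, sch, doc, nodes, "t"),
               class = "sbmlgraph_config_error")
})

test_that("a relationship over instance-less labels traces as none", {
  sch <- load_schema(arrows_json(
    nodes = list(list(id = "a", labels = "FunctionDefinition"),
                 list(id = "b", labels = "UnitDefinition")),
    relationships = list(list(type = "HAS_UNITS", from = "a", to = "b"))))
  g <- map_document(toy1_xml(), sch, tag = "t")
  tr <- resolution_trace(g)
  expect_equal(nrow(g$relationships), 0L)
  expect_equal(tr$strategy, "none")
  expect_equal(tr$n_edges, 0L)
})

test_that("mapping is deterministic across repeated runs", {
  xml <- generate_model(fixture_spec(2, 6, 4, 2, 2, packages = "fbc",
                                     seed = 5))
  g1 <- map_document(xml, gem_schema(), tag = "t")
  g2 <- map_document(xml, gem_schema(), tag = "t")
  expect_identical(g1$nodes, g2$nodes)
  expect_identical(g1$relationships, g2$relationships)
  expect_identical(resolution_trace(g1), resolution_trace(g2))
})

test_that("imports under different tags never share keys or edges", {
  xml <- toy1_xml()
  ga <- map_document(xml, metabolic_schema(), tag = "A")
  gb <- map_document(xml, metabolic_schema(), tag = "B")
  expect_equal(length(intersect(ga$nodes$key, gb$nodes$key)), 0L)
  merged <- merge_graphs(ga, gb)
  expect_equal(nrow(merged$nodes), nrow(ga$nodes) + nrow(gb$nodes))
  # every edge stays within its tag
  rels <- tidy(merged, "relationships")
  src_tag <- rels$tag
  tgt_tag <- purrr::map_chr(
    strsplit(merged$relationships$target, "\u001f", fixed = TRUE), 3)
  expect_equal(src_tag, tgt_tag)
})

test_that("default tag falls back to the model id", {
  g <- map_document(toy1_xml(), metabolic_schema())
  expect_equal(unique(g$nodes$tag), "synthmodel")
})

test_that("dangling participant references warn, never link to the missing
           id, and stay oracle-consistent", {
  xml <- sub('species="S1"', 'species="missing"', toy1_xml(), fixed = TRUE)
  expect_warning(g <- map_document(xml, metabolic_schema(), tag = "t"),
                 class = "sbmlgraph_dangling_reference")
  rels <- tidy(g, "relationships")
  expect_false(any(rels$target_id == "missing"))
  expect_equal(sum(rels$type == "HAS_PRODUCT"), 1L)
  suppressWarnings(
    expect_stats_equal(graph_stats(g), ground_truth(xml, metabolic_schema())))
})
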