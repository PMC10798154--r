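test_that("a single-node graph emits exactly one node statement", {
  g <- upsert_node(property_graph(),
                   list(label = "Species", id = "S1", tag = "t"))
  script <- to_cypher(g)
  expect_equal(nrow(script), 1L)
  expect_match(script$statement[[1]], "^UNWIND \\$rows AS row MERGE")
  expect_equal(length(script$params[[1]]$rows), 1L)
})

test_that("the toy graph batches into one statement per label and type", {
  g <- map_document(toy1_xml(), metabolic_schema(), tag = "t")
  script <- to_cypher(g, batch_size = 1000L)
  node_stmts <- grep("MERGE \\(n:", script$statement)
  rel_stmts <- grep("MERGE \\(a\\)", script$statement)
  expect_equal(length(node_stmts), 3L)
  expect_equal(length(rel_stmts), 3L)
  expect_equal(nrow(script), 6L)
  # nodes before relationships
  expect_true(max(node_stmts) < min(rel_stmts))
  expect_error(to_cypher(g, batch_size = 0),
               class = "sbmlgraph_config_error")
})

test_that("statement text is bit-stable and data travels as parameters", {
  g <- map_document(toy1_xml(), metabolic_schema(), tag = "t")
  s1 <- to_cypher(g)
  s2 <- to_cypher(g)
  expect_identical(s1$statement, s2$statement)
  expect_identical(s1$params, s2$params)
  # no node id appears in statement text
  expect_false(any(grepl("S1|S2|C1", s1$statement)))
})

test_that("small batch sizes split payloads without changing the result", {
  g <- map_document(generate_model(fixture_spec(2, 6, 4, 2, 2, seed = 4)),
                    metabolic_schema(), tag = "t")
  big <- execute_cypher(to_cypher(g, batch_size = 1000L))
  small <- execute_cypher(to_cypher(g, batch_size = 2L))
  expect_equal(graph_stats(store_to_graph(small)),
               graph_stats(store_to_graph(big)))
  expect_gt(nrow(to_cypher(g, batch_size = 2L)), nrow(to_cypher(g)))
})

test_that("replaying a script is idempotent under MERGE semantics", {
  g <- map_document(toy1_xml(), metabolic_schema(), tag = "t")
  script <- to_cypher(g)
  once <- execute_cypher(script)
  stats_once <- graph_stats(store_to_graph(once))
  twice <- execute_cypher(script, once)
  stats_twice <- graph_stats(store_to_graph(twice))
  expect_equal(stats_twice, stats_once)
  expect_equal(stats_once, graph_stats(g))
  expect_equal(once$nodes_created, 4L)
  expect_equal(twice$nodes_merged, 4L)
  expect_equal(twice$rels_merged, 4L)
})

test_that("extra labels survive emission and replay", {
  sch <- load_schema(arrows_json(list(
    list(id = "a", labels = c("Species", "Metabolite"),
         properties = list(id = "string")))))
  g <- map_document(toy1_xml(), sch, tag = "t")
  script <- to_cypher(g)
  expect_match(script$statement[[1]], "SET n:`Metabolite`")
  store <- execute_cypher(script)
  labels <- store$nodes[[1]]$labels
  expect_equal(labels, c("Species", "Metabolite"))
})

test_that("dry-run loads write the script and sidecar, nothing else", {
  g <- map_document(toy1_xml(), metabolic_schema(), tag = "t")
  out <- file.path(withr::local_tempdir(), "out.cypher")
  report <- load_graph(g, import_config(dry_run = out))
  expect_true(file.exists(out))
  expect_true(file.exists(paste0(out, ".params.jsonl")))
  expect_equal(length(readLines(out)), 6L)
  expect_equal(length(readLines(paste0(out, ".params.jsonl"))), 6L)
  expect_true(report$dry_run)
  expect_equal(report$statements, 6L)
  # each sidecar line is valid JSON with a rows payload
  payloads <- purrr::map(readLines(paste0(out, ".params.jsonl")),
                         jsonlite::fromJSON, simplifyVector = FALSE)
  expect_true(all(purrr::map_lgl(payloads, function(p) "rows" %in% names(p))))
})

test_that("loading through an executor reports created then merged counts", {
  g <- map_document(toy1_xml(), metabolic_schema(), tag = "t")
  store <- cypher_store()
  cfg <- import_config(executor = store_executor(store))
  r1 <- load_graph(g, cfg)
  expect_equal(r1$nodes_created, 4L)
  expect_equal(r1$relationships_created, 4L)
  r2 <- load_graph(g, cfg)
  expect_equal(r2$nodes_created, 0L)
  expect_equal(r2$nodes_merged, 4L)
  expect_equal(r2$relationships_merged, 4L)
})

test_that("a load without any database route fails before writing", {
  g <- map_document(toy1_xml(), metabolic_schema(), tag = "t")
  expect_error(load_graph(g, import_config()),
               class = "sbmlgraph_connection_error")
  expect_error(load_graph(g, import_config(uri = "bolt://nowhere:7687")),
               class = "sbmlgraph_connection_error")
  expect_error(import_config(dry_run = "x", uri = "bolt://y"),
               class = "sbmlgraph_config_error")
})

test_that("a failing executor reports the failed batch index", {
  g <- map_document(toy1_xml(), metabolic_schema(), tag = "t")
  boom <- function(statement, params) stop("socket reset")
  expect_error(load_graph(g, import_config(executor = boom)),
               class = "sbmlgraph_load_error", regexp = "batch 1")
})

test_that("JSON and GraphML exports round-trip field by field", {
  g <- map_document(generate_model(
    fixture_spec(2, 4, 3, 1, 1, packages = "fbc", seed = 2)),
    gem_schema(), tag = "t")
  for (fmt in c("json", "graphml")) {
    back <- import_graph(export_graph(g, fmt), fmt)
    expect_equal(sort(back$nodes$key), sort(g$nodes$key), info = fmt)
    ord_b <- order(back$nodes$key)
    ord_g <- order(g$nodes$key)
    expect_equal(back$nodes$labels[ord_b], g$nodes$labels[ord_g], info = fmt)
    bp <- back$nodes$properties[ord_b]
    gp <- g$nodes$properties[ord_g]
    for (i in seq_along(bp)) {
      expect_equal(bp[[i]][sort(names(bp[[i]]))],
                   gp[[i]][sort(names(gp[[i]]))], info = fmt)
    }
    key_of <- function(r) paste(r$type, r$source, r$target)
    expect_setequal(key_of(back$relationships), key_of(g$relationships))
  }
  expect_error(export_graph(g, "xlsx"))
})

test_that("empty graphs export to valid empty documents", {
  g <- property_graph()
  j <- export_graph(g, "json")
  expect_equal(glance(import_graph(j, "json"))$n_nodes, 0L)
  gm <- export_graph(g, "graphml")
  expect_equal(glance(import_graph(gm, "graphml"))$n_nodes, 0L)
})

test_that("GraphML output declares every referenced data key", {
  g <- map_document(toy1_xml(), metabolic_schema(), tag = "t")
  doc <- xml2::read_xml(export_graph(g, "graphml"))
  expect_equal(xml2::xml_name(doc), "graphml")
  declared <- xml2::xml_attr(
    xml2::xml_find_all(doc, "//*[local-name()='key']"), "id")
  used <- unique(xml2::xml_attr(
    xml2::xml_find_all(doc, "//*[local-name()='data']"), "key"))
  expect_true(all(used %in% declared))
  # typed attributes declared as boolean/double where appropriate
  types <- xml2::xml_attr(
    xml2::xml_find_all(doc, "//*[local-name()='key']"), "attr.type")
  expect_true("boolean" %in% types)  # reversible
})
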