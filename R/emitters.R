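# Materialization of a property graph: parameterized Cypher (batched UNWIND
# over MERGE), a pluggable load contract, and JSON/GraphML exports. No data
# value is ever interpolated into statement text; everything travels in the
# parameter payload, so statements are bit-stable for a given graph and
# batch size.

#' Emit an idempotent, parameterized Cypher script
#'
#' Node statements come first, grouped by label stack and batched into
#' `UNWIND $rows` payloads; each row merges on `{id, tag}` under the primary
#' label and then sets the remaining properties (extra labels are set
#' afterwards). Relationship statements follow, grouped by (type, source
#' label, target label): both endpoints are matched on `{id, tag}` and the
#' typed edge is merged. Replaying the script against the same store is a
#' no-op by construction of MERGE.
#'
#' @param graph A `property_graph`.
#' @param batch_size Rows per UNWIND payload (default 1000).
#' @param constraints Also emit composite-uniqueness constraint preamble
#'   statements, one per label (default `FALSE`).
#' @return A `cypher_script`: tibble with columns `statement` and `params`
#'   (list of payloads), with the batch size as an attribute.
#' @examples
#' g <- map_document(generate_model(fixture_spec()),
#'                   example_schema("metabolic"), tag = "toy1")
#' to_cypher(g)$statement
#' @export
to_cypher <- function(graph, batch_size = 1000L, constraints = FALSE) {
  stopifnot(inherits(graph, "property_graph"))
  if (!is.numeric(batch_size) || length(batch_size) != 1L || batch_size < 1) {
    abort("`batch_size` must be a positive integer.",
          class = "sbmlgraph_config_error")
  }
  batch_size <- as.integer(batch_size)
  statements <- character()
  params <- list()

  add <- function(stmt, payload) {
    statements[[length(statements) + 1L]] <<- stmt
    params[[length(params) + 1L]] <<- payload
  }

  nodes <- graph$nodes
  if (nrow(nodes) > 0L) {
    stack_id <- purrr::map_chr(nodes$labels, paste, collapse = "\u001f")
    for (stack in unique(stack_id)) {
      sel <- nodes[stack_id == stack, ]
      labels <- sel$labels[[1]]
      if (constraints) {
        add(paste0("CREATE CONSTRAINT IF NOT EXISTS FOR (n:",
                   backtick(labels[[1]]),
                   ") REQUIRE (n.id, n.tag) IS UNIQUE"),
            list())
      }
      extra <- if (length(labels) > 1L) {
        paste0(" SET n", paste0(":", backtick(labels[-1]), collapse = ""))
      } else ""
      stmt <- paste0(
        "UNWIND $rows AS row MERGE (n:", backtick(labels[[1]]),
        " {id: row.id, tag: row.tag}) SET n += row.props", extra)
      rows <- purrr::pmap(sel[, c("id", "tag", "properties")],
                          function(id, tag, properties) {
        list(id = id, tag = tag,
             props = properties[setdiff(names(properties), c("id", "tag"))])
      })
      for (b in chunk_list(rows, batch_size)) add(stmt, list(rows = b))
    }
  }

  rels <- graph$relationships
  if (nrow(rels) > 0L) {
    src <- key_parts(rels$source)
    tgt <- key_parts(rels$target)
    group <- paste(rels$type, src$label, tgt$label, sep = "\u001f")
    for (grp in unique(group)) {
      sel <- which(group == grp)
      type <- rels$type[[sel[[1]]]]
      stmt <- paste0(
        "UNWIND $rows AS row MATCH (a:", backtick(src$label[[sel[[1]]]]),
        " {id: row.source_id, tag: row.source_tag}) MATCH (b:",
        backtick(tgt$label[[sel[[1]]]]),
        " {id: row.target_id, tag: row.target_tag}) MERGE (a)-[r:",
        backtick(type), "]->(b) SET r += row.props")
      rows <- purrr::map(sel, function(i) {
        list(source_id = src$id[[i]], source_tag = src$tag[[i]],
             target_id = tgt$id[[i]], target_tag = tgt$tag[[i]],
             props = rels$properties[[i]])
      })
      for (b in chunk_list(rows, batch_size)) add(stmt, list(rows = b))
    }
  }

  script <- tibble::tibble(statement = statements, params = params)
  attr(script, "batch_size") <- batch_size
  class(script) <- c("cypher_script", class(script))
  script
}

backtick <- function(x) paste0("`", gsub("`", "``", x), "`")

chunk_list <- function(x, size) {
  if (length(x) == 0L) return(list())
  split(x, ceiling(seq_along(x) / size))
}

key_parts <- function(keys) {
  parts <- strsplit(keys, "\u001f", fixed = TRUE)
  list(label = purrr::map_chr(parts, 1),
       id = purrr::map_chr(parts, 2),
       tag = purrr::map_chr(parts, 3))
}

#' Write a Cypher script to disk
#'
#' One statement per line; parameters go to a JSON-lines sidecar
#' (`<path>.params.jsonl`), one payload per statement line.
#'
#' @param script A `cypher_script`.
#' @param path Output file for the statements.
#' @return `path`, invisibly.
#' @export
write_cypher <- function(script, path) {
  stopifnot(inherits(script, "cypher_script"))
  writeLines(script$statement, path, useBytes = TRUE)
  sidecar <- paste0(path, ".params.jsonl")
  lines <- purrr::map_chr(script$params, function(p)
    as.character(jsonlite::toJSON(p, auto_unbox = TRUE, null = "null",
                                  digits = NA)))
  writeLines(lines, sidecar, useBytes = TRUE)
  invisible(path)
}

# --- in-memory Cypher MERGE interpreter -----------------------------------
# A deliberately minimal executor understanding exactly the statement shapes
# to_cypher() emits. It gives the package a database-free way to verify that
# the emitted script is idempotent and count-equivalent to the source graph.

#' Create an empty in-memory Cypher store
#'
#' @return A `cypher_store` environment holding `nodes` and `rels` maps plus
#'   created/merged counters.
#' @export
cypher_store <- function() {
  st <- new.env(parent = emptyenv())
  st$nodes <- list()
  st$rels <- list()
  st$nodes_created <- 0L
  st$nodes_merged <- 0L
  st$rels_created <- 0L
  st$rels_merged <- 0L
  class(st) <- "cypher_store"
  st
}

NODE_STMT_RE <- paste0(
  "^UNWIND \\$rows AS row MERGE \\(n:`(.+?)` \\{id: row\\.id, ",
  "tag: row\\.tag\\}\\) SET n \\+= row\\.props(.*)$")
REL_STMT_RE <- paste0(
  "^UNWIND \\$rows AS row MATCH \\(a:`(.+?)` \\{id: row\\.source_id, ",
  "tag: row\\.source_tag\\}\\) MATCH \\(b:`(.+?)` \\{id: row\\.target_id, ",
  "tag: row\\.target_tag\\}\\) MERGE \\(a\\)-\\[r:`(.+?)`\\]->\\(b\\) ",
  "SET r \\+= row\\.props$")

#' Execute a Cypher script against an in-memory store
#'
#' Interprets the MERGE/SET statement shapes produced by [to_cypher()]
#' (constraint preambles are accepted and ignored), updating the store with
#' Cypher MERGE semantics: match on key, create when absent, then overwrite
#' properties. Used to verify idempotence without a live database.
#'
#' @param script A `cypher_script`.
#' @param store A `cypher_store`; a fresh one by default.
#' @return The updated `cypher_store`.
#' @export
execute_cypher <- function(script, store = cypher_store()) {
  stopifnot(inherits(script, "cypher_script"), inherits(store, "cypher_store"))
  for (i in seq_len(nrow(script))) {
    execute_cypher_statement(store, script$statement[[i]],
                             script$params[[i]])
  }
  store
}

execute_cypher_statement <- function(store, stmt, params) {
  if (grepl("^CREATE CONSTRAINT", stmt)) return(invisible(store))
  m <- regmatches(stmt, regexec(NODE_STMT_RE, stmt))[[1]]
  if (length(m) > 0L) {
    label <- gsub("``", "`", m[[2]])
    extra <- regmatches(m[[3]], gregexpr("`(.+?)`", m[[3]]))[[1]]
    extra <- gsub("`", "", extra)
    for (row in params$rows) {
      key <- paste(label, row$id, row$tag, sep = "\u001f")
      existing <- store$nodes[[key]]
      if (is.null(existing)) {
        store$nodes_created <- store$nodes_created + 1L
        existing <- list(labels = c(label, extra),
                         props = list(id = row$id, tag = row$tag))
      } else {
        store$nodes_merged <- store$nodes_merged + 1L
        existing$labels <- union(existing$labels, extra)
      }
      for (nm in names(row$props)) existing$props[[nm]] <- row$props[[nm]]
      store$nodes[[key]] <- existing
    }
    return(invisible(store))
  }
  m <- regmatches(stmt, regexec(REL_STMT_RE, stmt))[[1]]
  if (length(m) > 0L) {
    src_label <- gsub("``", "`", m[[2]])
    tgt_label <- gsub("``", "`", m[[3]])
    type <- gsub("``", "`", m[[4]])
    for (row in params$rows) {
      a <- paste(src_label, row$source_id, row$source_tag, sep = "\u001f")
      b <- paste(tgt_label, row$target_id, row$target_tag, sep = "\u001f")
      if (is.null(store$nodes[[a]]) || is.null(store$nodes[[b]])) next
      rkey <- paste(type, a, b, sep = "")
      existing <- store$rels[[rkey]]
      if (is.null(existing)) {
        store$rels_created <- store$rels_created + 1L
        existing <- list(type = type, source = a, target = b, props = list())
      } else {
        store$rels_merged <- store$rels_merged + 1L
      }
      for (nm in names(row$props)) existing$props[[nm]] <- row$props[[nm]]
      store$rels[[rkey]] <- existing
    }
    return(invisible(store))
  }
  abort(paste0("Unrecognized statement shape: ", substr(stmt, 1, 60), "..."),
        class = "sbmlgraph_cypher_error")
}

#' Convert an in-memory Cypher store back to a property graph
#'
#' @param store A `cypher_store`.
#' @return A `property_graph` with the store's contents.
#' @export
store_to_graph <- function(store) {
  stopifnot(inherits(store, "cypher_store"))
  g <- property_graph()
  for (key in names(store$nodes)) {
    nd <- store$nodes[[key]]
    parts <- strsplit(key, "\u001f", fixed = TRUE)[[1]]
    g <- upsert_node(g, list(label = parts[[1]], id = parts[[2]],
                             tag = parts[[3]], labels = nd$labels,
                             properties = nd$props))
  }
  for (rkey in names(store$rels)) {
    rl <- store$rels[[rkey]]
    g <- upsert_relationship(g, list(type = rl$type, source = rl$source,
                                     target = rl$target,
                                     properties = rl$props))
  }
  g
}

# --- load contract --------------------------------------------------------

#' Run settings for a graph load
#'
#' @param tag Import tag override (`NULL`: the mapper's default).
#' @param dry_run Path to write the Cypher script to instead of executing
#'   (mutually exclusive with a connection/executor).
#' @param uri,database,user,password_env Connection settings for a Neo4j
#'   server; the password is only ever read from the environment variable
#'   named by `password_env`, never passed literally.
#' @param batch_size Rows per UNWIND payload.
#' @param executor Optional function `(statement, params) -> NULL` executing
#'   one statement transactionally — the seam through which a live driver
#'   (or the in-memory store, see [store_executor()]) is plugged in.
#' @return An `import_config` list.
#' @export
import_config <- function(tag = NULL, dry_run = NULL, uri = NULL,
                          database = "neo4j", user = NULL,
                          password_env = NULL, batch_size = 1000L,
                          executor = NULL) {
  if (!is.null(dry_run) && (!is.null(uri) || !is.null(executor))) {
    abort("`dry_run` and a connection/executor are mutually exclusive.",
          class = "sbmlgraph_config_error")
  }
  structure(list(tag = tag, dry_run = dry_run, uri = uri,
                 database = database, user = user,
                 password_env = password_env,
                 batch_size = as.integer(batch_size), executor = executor),
            class = "import_config")
}

#' Executor backed by an in-memory Cypher store
#'
#' @param store A `cypher_store`.
#' @return A function suitable for `import_config(executor = )`.
#' @export
store_executor <- function(store) {
  force(store)
  function(statement, params) {
    execute_cypher_statement(store, statement, params)
    invisible(NULL)
  }
}

#' Load a property graph through the Cypher contract
#'
#' In dry-run mode the script is written to the configured path (plus the
#' parameter sidecar) and no connection is attempted. Otherwise each
#' statement is executed through the configured executor, one batch per
#' transaction, failing fast: a mid-run failure aborts with the index of the
#' failed batch and no retry.
#'
#' @param graph A `property_graph`.
#' @param config An [import_config()].
#' @return A `load_report` tibble: nodes/relationships created and merged,
#'   plus the statement count.
#' @export
load_graph <- function(graph, config = import_config()) {
  stopifnot(inherits(graph, "property_graph"),
            inherits(config, "import_config"))
  script <- to_cypher(graph, batch_size = config$batch_size)
  if (!is.null(config$dry_run)) {
    write_cypher(script, config$dry_run)
    report <- tibble::tibble(
      nodes_created = 0L, nodes_merged = 0L,
      relationships_created = 0L, relationships_merged = 0L,
      statements = nrow(script), dry_run = TRUE)
    class(report) <- c("load_report", class(report))
    return(report)
  }
  executor <- config$executor
  store <- NULL
  if (is.null(executor)) {
    if (is.null(config$uri)) {
      abort(paste0("No way to reach a database: provide `dry_run`, ",
                   "`executor`, or a connection `uri`."),
            class = "sbmlgraph_connection_error")
    }
    abort(paste0("No driver available for uri '", config$uri,
                 "'; supply an `executor` wrapping your connection."),
          class = "sbmlgraph_connection_error")
  }
  counts_before <- NULL
  if (!is.null(environment(executor)$store)) {
    store <- environment(executor)$store
    counts_before <- c(store$nodes_created, store$nodes_merged,
                       store$rels_created, store$rels_merged)
  }
  for (i in seq_len(nrow(script))) {
    tryCatch(
      executor(script$statement[[i]], script$params[[i]]),
      error = function(e) {
        abort(paste0("Load failed at batch ", i, ": ",
                     conditionMessage(e)),
              class = "sbmlgraph_load_error")
      }
    )
  }
  if (!is.null(store)) {
    d <- c(store$nodes_created, store$nodes_merged,
           store$rels_created, store$rels_merged) - counts_before
    report <- tibble::tibble(
      nodes_created = d[[1]], nodes_merged = d[[2]],
      relationships_created = d[[3]], relationships_merged = d[[4]],
      statements = nrow(script), dry_run = FALSE)
  } else {
    report <- tibble::tibble(
      nodes_created = NA_integer_, nodes_merged = NA_integer_,
      relationships_created = NA_integer_, relationships_merged = NA_integer_,
      statements = nrow(script), dry_run = FALSE)
  }
  class(report) <- c("load_report", class(report))
  report
}

# --- JSON / GraphML export ------------------------------------------------

#' Export a property graph to a document
#'
#' The JSON dialect is `{nodes: [{label, id, tag, labels, properties}],
#' relationships: [{type, source: {label, id, tag}, target: {...},
#' properties}]}`. GraphML output declares one `<key>` per property name
#' with its inferred `attr.type` (`string`, `double`, `boolean`); node ids
#' are opaque and label stacks travel as a JSON-encoded data field. Both
#' formats round-trip losslessly through [import_graph()].
#'
#' @param graph A `property_graph`.
#' @param format `"json"` or `"graphml"`.
#' @return Document text (a length-1 character vector).
#' @export
export_graph <- function(graph, format = c("json", "graphml")) {
  stopifnot(inherits(graph, "property_graph"))
  format <- match.arg(format)
  if (format == "json") return(export_graph_json(graph))
  export_graph_graphml(graph)
}

export_graph_json <- function(graph) {
  nodes <- purrr::pmap(graph$nodes[, c("label", "id", "tag", "labels",
                                       "properties")],
                       function(label, id, tag, labels, properties) {
    list(label = label, id = id, tag = tag, labels = as.list(labels),
         properties = properties)
  })
  src <- key_parts(graph$relationships$source)
  tgt <- key_parts(graph$relationships$target)
  rels <- purrr::map(seq_len(nrow(graph$relationships)), function(i) {
    list(type = graph$relationships$type[[i]],
         source = list(label = src$label[[i]], id = src$id[[i]],
                       tag = src$tag[[i]]),
         target = list(label = tgt$label[[i]], id = tgt$id[[i]],
                       tag = tgt$tag[[i]]),
         properties = graph$relationships$properties[[i]])
  })
  as.character(jsonlite::toJSON(list(nodes = nodes, relationships = rels),
                                auto_unbox = TRUE, null = "null",
                                digits = NA, pretty = TRUE))
}

graphml_type <- function(v) {
  if (is.logical(v)) "boolean" else if (is.numeric(v)) "double" else "string"
}

export_graph_graphml <- function(graph) {
  doc <- xml2::xml_new_root(
    "graphml",
    xmlns = "http://graphml.graphdrawing.org/xmlns")
  prop_types <- list()
  note_props <- function(props, domain) {
    for (nm in names(props)) {
      k <- paste(domain, nm, sep = "\u001f")
      prop_types[[k]] <<- graphml_type(props[[nm]])
    }
  }
  purrr::walk(graph$nodes$properties, note_props, domain = "node")
  purrr::walk(graph$relationships$properties, note_props, domain = "edge")

  add_key <- function(id, domain, name, type) {
    xml2::xml_add_child(doc, "key", id = id, `for` = domain,
                        attr.name = name, attr.type = type)
  }
  add_key("nlabel", "node", "label", "string")
  add_key("nlabels", "node", "labels", "string")
  add_key("etype", "edge", "type", "string")
  for (k in names(prop_types)) {
    parts <- strsplit(k, "\u001f", fixed = TRUE)[[1]]
    add_key(paste0("p", make_graphml_id(k)), parts[[1]], parts[[2]],
            prop_types[[k]])
  }

  gr <- xml2::xml_add_child(doc, "graph", id = "G", edgedefault = "directed")
  data_child <- function(parent, key, value) {
    d <- xml2::xml_add_child(parent, "data", key = key)
    xml2::xml_text(d) <- encode_graphml_value(value)
  }
  for (i in seq_len(nrow(graph$nodes))) {
    nd <- xml2::xml_add_child(gr, "node",
                              id = make_graphml_id(graph$nodes$key[[i]]))
    data_child(nd, "nlabel", graph$nodes$label[[i]])
    data_child(nd, "nlabels",
               as.character(jsonlite::toJSON(graph$nodes$labels[[i]])))
    props <- graph$nodes$properties[[i]]
    for (nm in names(props)) {
      data_child(nd, paste0("p", make_graphml_id(
        paste("node", nm, sep = "\u001f"))), props[[nm]])
    }
  }
  for (i in seq_len(nrow(graph$relationships))) {
    ed <- xml2::xml_add_child(
      gr, "edge",
      source = make_graphml_id(graph$relationships$source[[i]]),
      target = make_graphml_id(graph$relationships$target[[i]]))
    data_child(ed, "etype", graph$relationships$type[[i]])
    props <- graph$relationships$properties[[i]]
    for (nm in names(props)) {
      data_child(ed, paste0("p", make_graphml_id(
        paste("edge", nm, sep = "\u001f"))), props[[nm]])
    }
  }
  as.character(doc)
}

# GraphML ids must be XML NMTOKEN-safe; percent-encode anything else.
make_graphml_id <- function(x) {
  vapply(x, function(s) {
    chars <- strsplit(s, "", fixed = FALSE)[[1]]
    paste(vapply(chars, function(ch) {
      if (grepl("[A-Za-z0-9_.-]", ch)) ch else
        paste0("%", sprintf("%02X", utf8ToInt(ch)))
    }, character(1)), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

unmake_graphml_id <- function(x) {
  vapply(x, function(s) {
    m <- gregexpr("%[0-9A-F]{2}", s)[[1]]
    if (m[[1]] == -1) return(s)
    utils::URLdecode(s)
  }, character(1), USE.NAMES = FALSE)
}

encode_graphml_value <- function(v) {
  if (is.logical(v)) tolower(as.character(v)) else
    format(v, scientific = FALSE, trim = TRUE)
}

decode_typed_value <- function(txt, type) {
  switch(type,
         boolean = identical(txt, "true"),
         double = as.numeric(txt),
         txt)
}

#' Import a property graph from an exported document
#'
#' Inverse of [export_graph()]: `import_graph(export_graph(g, f), f)` equals
#' `g` field by field.
#'
#' @param text Document text or a file path.
#' @param format `"json"` or `"graphml"`.
#' @return A `property_graph`.
#' @export
import_graph <- function(text, format = c("json", "graphml")) {
  format <- match.arg(format)
  txt <- read_text_arg(text)
  if (format == "json") return(import_graph_json(txt))
  import_graph_graphml(txt)
}

import_graph_json <- function(txt) {
  doc <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  g <- property_graph()
  for (nd in doc$nodes %||% list()) {
    g <- upsert_node(g, list(label = nd$label, id = nd$id, tag = nd$tag,
                             labels = as.character(unlist(nd$labels)),
                             properties = simplify_props(nd$properties)))
  }
  for (rl in doc$relationships %||% list()) {
    g <- upsert_relationship(g, list(
      type = rl$type,
      source = node_key(rl$source$label, rl$source$id, rl$source$tag),
      target = node_key(rl$target$label, rl$target$id, rl$target$tag),
      properties = simplify_props(rl$properties)))
  }
  g
}

simplify_props <- function(props) {
  purrr::map(props %||% list(), function(v) {
    if (is.list(v)) unlist(v) else v
  })
}

import_graph_graphml <- function(txt) {
  doc <- xml2::read_xml(txt)
  keys <- xml2::xml_find_all(doc, ".//*[local-name()='key']")
  key_info <- list()
  for (k in keys) {
    key_info[[xml2::xml_attr(k, "id")]] <- list(
      name = xml2::xml_attr(k, "attr.name"),
      type = xml2::xml_attr(k, "attr.type"))
  }
  read_data <- function(el) {
    out <- list()
    for (d in xml2::xml_find_all(el, "./*[local-name()='data']")) {
      out[[xml2::xml_attr(d, "key")]] <- xml2::xml_text(d)
    }
    out
  }
  g <- property_graph()
  for (nd in xml2::xml_find_all(doc, ".//*[local-name()='node']")) {
    data <- read_data(nd)
    labels <- as.character(jsonlite::fromJSON(data$nlabels))
    props <- list()
    for (dk in setdiff(names(data), c("nlabel", "nlabels"))) {
      info <- key_info[[dk]]
      props[[info$name]] <- decode_typed_value(data[[dk]], info$type)
    }
    g <- upsert_node(g, list(label = data$nlabel, id = props$id,
                             tag = props$tag, labels = labels,
                             properties = props))
  }
  for (ed in xml2::xml_find_all(doc, ".//*[local-name()='edge']")) {
    data <- read_data(ed)
    props <- list()
    for (dk in setdiff(names(data), "etype")) {
      info <- key_info[[dk]]
      props[[info$name]] <- decode_typed_value(data[[dk]], info$type)
    }
    g <- upsert_relationship(g, list(
      type = data$etype,
      source = unmake_graphml_id(xml2::xml_attr(ed, "source")),
      target = unmake_graphml_id(xml2::xml_attr(ed, "target")),
      properties = props))
  }
  g
}
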