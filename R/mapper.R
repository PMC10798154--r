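# The extraction engine. Node extraction matches schema labels to component
# kinds by canonical name. Each schema relationship is resolved per source
# instance by three strategies, tried most-specific first:
#   1. target-name: an attribute of the source named after the target label
#      holds the target's id (Species.compartment -> Compartment).
#   2. relationship-name: an attribute or direct listOf* child named after the
#      (verb-stripped) relationship type supplies target ids
#      (LocalParameter.units via HAS_UNITS; listOfProducts via HAS_PRODUCT).
#   3. containment: target instances nested beneath the source, or referenced
#      by id from any attribute of a nested element (Reaction -> GeneProduct
#      through geneProductRef).
# The first strategy returning a non-empty result wins for that source.

#' Deterministic fallback identifier for id-less components
#'
#' Components such as Level 2 speciesReference or eventAssignment elements
#' often carry no `id`; graph nodes still need a stable merge key. The
#' surrogate is the record's document path with `listOf*` wrappers and the
#' model root elided, e.g. `"event[0]/eventAssignment[0]"`. It is unique per
#' document and identical across re-parses of the same bytes.
#'
#' @param record A component record.
#' @return A surrogate id string.
#' @export
surrogate_key <- function(record) {
  record$spath
}

record_local_id <- function(record) {
  record$id %||% surrogate_key(record)
}

#' Extract graph nodes for every schema-selected component
#'
#' For each schema node, every document record whose kind matches the first
#' label (canonical comparison) becomes one graph node carrying the
#' schema-listed properties found on the record (absent ones omitted), the
#' import `tag`, and the node key (primary label, component id or surrogate,
#' tag). Kinds not selected by the schema produce nothing.
#'
#' @param doc An `sbml_document`.
#' @param schema An `sbml_schema`.
#' @param tag Non-empty import tag; see [map_document()].
#' @return A tibble of nodes (columns `key`, `label`, `id`, `tag`, `labels`,
#'   `properties`).
#' @export
extract_nodes <- function(doc, schema, tag) {
  stopifnot(inherits(doc, "sbml_document"), inherits(schema, "sbml_schema"),
            is.character(tag), length(tag) == 1L, nzchar(tag))
  rows <- list()
  for (i in seq_len(nrow(schema$nodes))) {
    labels <- schema$nodes$labels[[i]]
    primary <- labels[[1]]
    declared <- names(schema$nodes$properties[[i]])
    for (rec in records_of_kind(doc, primary)) {
      props <- list()
      for (p in declared) {
        v <- attribute_value(rec, p)
        if (!is.null(v)) props[[p]] <- v
      }
      lid <- record_local_id(rec)
      props$id <- lid
      props$tag <- tag
      rows[[length(rows) + 1L]] <- tibble::tibble(
        key = node_key(primary, lid, tag),
        label = primary, id = lid, tag = tag,
        labels = list(labels), properties = list(props)
      )
    }
  }
  if (length(rows) == 0L) return(empty_nodes())
  dplyr::bind_rows(rows)
}

node_key <- function(label, id, tag) {
  paste(label, id, tag, sep = "\u001f")
}

# --- resolution strategies ------------------------------------------------

#' Resolve a relationship by the target component's name (strategy 1)
#'
#' Fires when the source record has an attribute named after the target label
#' whose value is the id of a target-kind record, e.g. a species'
#' `compartment` attribute naming its Compartment.
#'
#' @param source A component record.
#' @param target_label Schema label of the target component.
#' @param doc The owning `sbml_document`.
#' @return Character vector of target ids (length 0 or 1). A dangling
#'   reference (attribute present, no such target) yields length 0 with a
#'   warning.
#' @export
resolve_by_target_name <- function(source, target_label, doc) {
  v <- attribute_value(source, target_label)
  if (is.null(v) || !is.character(v) && !is.numeric(v)) return(character())
  v <- as.character(v)
  ids <- kind_ids(doc, target_label)
  if (v %in% ids) return(v)
  warn(paste0("Dangling reference: ", source$kind, " '",
              record_local_id(source), "' attribute names ", target_label,
              " '", v, "' which does not exist."),
       class = "sbmlgraph_dangling_reference")
  character()
}

#' Resolve a relationship by the relationship's name (strategy 2)
#'
#' The relationship type, with leading HAS/IS/IN verb tokens stripped, is
#' matched (i) against a scalar attribute of the source whose value is a
#' target id (`HAS_UNITS` finds `units`), then (ii) against a direct
#' `listOf*` child of the source, singular/plural-insensitively
#' (`HAS_PRODUCT` finds `listOfProducts`); each member element then
#' contributes the value of its attribute named after the target label
#' (`species` for target Species). Values that are not ids of target-kind
#' records are dropped with a warning.
#'
#' @param source A component record.
#' @param rel_type Relationship type as drawn in the schema.
#' @param target_label Schema label of the target component.
#' @param doc The owning `sbml_document`.
#' @return Character vector of target ids, document order, de-duplicated.
#' @export
resolve_by_relationship_name <- function(source, rel_type, target_label, doc) {
  want <- normalize_relationship(rel_type)
  ids <- kind_ids(doc, target_label)

  # (i) scalar attribute named like the relationship
  nms <- names(source$attributes)
  if (length(nms) > 0L) {
    hit <- which(names_match_sp(normalize_name(nms), want))
    for (h in hit) {
      v <- source$attributes[[h]]
      if (!is.character(v) && !is.numeric(v)) next
      v <- as.character(v)
      if (v %in% ids) return(v)
      warn(paste0("Dangling reference: ", source$kind, " '",
                  record_local_id(source), "' attribute '", nms[[h]],
                  "' names missing ", target_label, " '", v, "'."),
           class = "sbmlgraph_dangling_reference")
    }
  }

  # (ii) direct listOf* child named like the relationship
  out <- character()
  tl_norm <- normalize_name(target_label)
  for (ci in source$children) {
    child <- doc$records[[ci]]
    if (!is_listof(child$kind)) next
    if (!names_match_sp(listof_content(child$kind), want)) next
    for (mi in child$children) {
      member <- doc$records[[mi]]
      mn <- names(member$attributes)
      if (length(mn) == 0L) next
      ai <- which(normalize_name(mn) == tl_norm)
      if (length(ai) == 0L) next
      v <- as.character(member$attributes[[ai[[1]]]])
      if (v %in% ids) {
        out <- c(out, v)
      } else {
        warn(paste0("Dangling reference: ", child$kind, " member names ",
                    "missing ", target_label, " '", v, "'."),
             class = "sbmlgraph_dangling_reference")
      }
    }
  }
  unique(out)
}

#' Resolve a relationship by containment (strategy 3)
#'
#' Phase 1 collects target-kind records nested beneath the source (a
#' reaction's localParameter inside its kineticLaw); `listOf*` wrappers are
#' never targets unless the schema names them explicitly. If phase 1 finds
#' nothing, phase 2 collects target-kind records whose id is referenced by
#' any attribute of any descendant of the source — this links a Reaction to
#' its GeneProducts through nested `geneProductRef` elements.
#'
#' @param source A component record.
#' @param target_label Schema label of the target component.
#' @param doc The owning `sbml_document`.
#' @return Character vector of target local ids (surrogates for id-less
#'   targets), de-duplicated, document order.
#' @export
resolve_by_containment <- function(source, target_label, doc) {
  tl_norm <- normalize_name(target_label)
  desc <- descendant_records(doc, source)
  # listOf* wrappers only match when the schema names one explicitly: a
  # matching canonical kind is a listOf iff the requested label is.
  direct <- purrr::keep(desc, function(r) normalize_name(r$kind) == tl_norm)
  if (length(direct) > 0L) {
    return(unique(purrr::map_chr(direct, record_local_id)))
  }
  ids <- kind_ids(doc, target_label)
  if (length(ids) == 0L) return(character())
  referenced <- character()
  for (r in desc) {
    for (v in r$attributes) {
      if ((is.character(v) || is.numeric(v)) && as.character(v) %in% ids) {
        referenced <- c(referenced, as.character(v))
      }
    }
  }
  ids[ids %in% referenced]
}

kind_ids <- function(doc, label) {
  recs <- records_of_kind(doc, label)
  ids <- purrr::map_chr(recs, function(r) r$id %||% NA_character_)
  ids[!is.na(ids)]
}

#' Resolve one schema relationship into graph edges
#'
#' For every source-label instance the strategies are tried in the fixed
#' order target-name, relationship-name, containment; the first non-empty
#' result supplies the targets. One edge of the schema's type is created per
#' (source, target) pair, directed source to target as drawn; duplicates
#' collapse. Edges whose target was not extracted as a node are dropped with
#' a warning. Declared relationship properties are read from the source
#' record by the usual property-matching rule.
#'
#' @param schema_rel One row of `schema$relationships` (a list with `type`,
#'   `source_key`, `target_key`, `properties`).
#' @param schema The owning `sbml_schema` (to look up endpoint labels).
#' @param doc An `sbml_document`.
#' @param nodes Node tibble from [extract_nodes()].
#' @param tag Import tag.
#' @return List with `relationships` (tibble `type`, `source`, `target`,
#'   `properties`) and `trace` (tibble `type`, `source_label`, `target_label`,
#'   `strategy`, `n_sources`, `n_resolved_sources`, `n_edges`; `strategy` is
#'   the strategy that fired, or `"none"`).
#' @export
resolve_relationship <- function(schema_rel, schema, doc, nodes, tag) {
  src_i <- match(schema_rel$source_key, schema$nodes$key)
  tgt_i <- match(schema_rel$target_key, schema$nodes$key)
  if (is.na(src_i) || is.na(tgt_i)) {
    abort(paste0("Relationship '", schema_rel$type,
                 "' endpoint label missing from schema."),
          class = "sbmlgraph_config_error")
  }
  src_label <- schema$nodes$labels[[src_i]][[1]]
  tgt_label <- schema$nodes$labels[[tgt_i]][[1]]
  declared <- names(schema_rel$properties %||% list())

  tgt_keys <- nodes$key[nodes$label == tgt_label]
  src_records <- records_of_kind(doc, src_label)

  strat_counts <- c(`target-name` = 0L, `relationship-name` = 0L,
                    containment = 0L, none = 0L)
  edges <- list()
  for (rec in src_records) {
    targets <- resolve_by_target_name(rec, tgt_label, doc)
    strategy <- "target-name"
    if (length(targets) == 0L) {
      targets <- resolve_by_relationship_name(rec, schema_rel$type,
                                              tgt_label, doc)
      strategy <- "relationship-name"
    }
    if (length(targets) == 0L) {
      targets <- resolve_by_containment(rec, tgt_label, doc)
      strategy <- "containment"
    }
    if (length(targets) == 0L) {
      strat_counts[["none"]] <- strat_counts[["none"]] + 1L
      next
    }
    strat_counts[[strategy]] <- strat_counts[[strategy]] + 1L
    props <- list()
    for (p in declared) {
      v <- attribute_value(rec, p)
      if (!is.null(v)) props[[p]] <- v
    }
    skey <- node_key(src_label, record_local_id(rec), tag)
    for (t in targets) {
      tkey <- node_key(tgt_label, t, tag)
      if (!(tkey %in% tgt_keys)) {
        warn(paste0("Edge '", schema_rel$type, "' to non-extracted ",
                    tgt_label, " '", t, "' dropped."),
             class = "sbmlgraph_dropped_edge")
        next
      }
      edges[[length(edges) + 1L]] <- tibble::tibble(
        type = schema_rel$type, source = skey, target = tkey,
        properties = list(props))
    }
  }
  rels <- if (length(edges) == 0L) empty_relationships() else
    dplyr::distinct(dplyr::bind_rows(edges),
                    .data$type, .data$source, .data$target, .keep_all = TRUE)
  fired <- strat_counts[setdiff(names(strat_counts), "none")]
  trace <- tibble::tibble(
    type = schema_rel$type, source_label = src_label,
    target_label = tgt_label,
    strategy = if (sum(fired) == 0L) "none" else names(which.max(fired)),
    n_sources = length(src_records),
    n_resolved_sources = sum(fired),
    n_edges = nrow(rels)
  )
  list(relationships = rels, trace = trace)
}

#' Map a full SBML document onto a property graph
#'
#' The package's central operation: applies the schema to the parsed
#' document, extracting one node per selected component instance and
#' resolving every drawn relationship (see [resolve_relationship()]). The
#' `tag` is stamped on every node key and node property so that several
#' models can be merged into one store without cross-linking.
#'
#' The result is deterministic: identical document bytes, schema and tag
#' yield an identical graph and identical resolution traces.
#'
#' @param doc An `sbml_document` (or SBML text/path, parsed on the fly).
#' @param schema An `sbml_schema` (or Arrows export text/path).
#' @param tag Non-empty import tag. Defaults to the model's `id` attribute,
#'   falling back to `"model"`.
#' @return A `property_graph`; its resolution traces are available via
#'   [resolution_trace()].
#' @examples
#' g <- map_document(generate_model(fixture_spec()),
#'                   example_schema("metabolic"), tag = "toy1")
#' graph_stats(g)
#' @export
map_document <- function(doc, schema, tag = NULL) {
  if (!inherits(doc, "sbml_document")) doc <- parse_document(doc)
  if (!inherits(schema, "sbml_schema")) schema <- load_schema(schema)
  tag <- tag %||% doc$records[[1]]$id %||% "model"
  nodes <- extract_nodes(doc, schema, tag)
  rels <- empty_relationships()
  traces <- list()
  if (nrow(schema$relationships) > 0L) {
    for (i in seq_len(nrow(schema$relationships))) {
      res <- resolve_relationship(as.list(schema$relationships[i, ]),
                                  schema, doc, nodes, tag)
      rels <- dplyr::bind_rows(rels, res$relationships)
      traces[[i]] <- res$trace
    }
    rels <- dplyr::distinct(rels, .data$type, .data$source, .data$target,
                            .keep_all = TRUE)
  }
  g <- new_property_graph(nodes, rels)
  attr(g, "trace") <- if (length(traces)) dplyr::bind_rows(traces) else
    empty_trace()
  g
}

#' Resolution trace of a mapped graph
#'
#' One row per schema relationship, recording which strategy resolved it
#' (`target-name`, `relationship-name`, `containment`, or `none`), how many
#' source instances existed, how many resolved, and how many edges resulted.
#'
#' @param graph A `property_graph` produced by [map_document()].
#' @return A tibble.
#' @export
resolution_trace <- function(graph) {
  attr(graph, "trace") %||% empty_trace()
}

empty_trace <- function() {
  tibble::tibble(type = character(), source_label = character(),
                 target_label = character(), strategy = character(),
                 n_sources = integer(), n_resolved_sources = integer(),
                 n_edges = integer())
}
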