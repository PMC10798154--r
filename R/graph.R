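# In-memory labeled property graph. Nodes and relationships live in two
# tibbles; node identity is the (primary label, local id, tag) triple and
# upserts merge by that key, mirroring a Cypher MERGE ... SET.

empty_nodes <- function() {
  tibble::tibble(key = character(), label = character(), id = character(),
                 tag = character(), labels = list(), properties = list())
}

empty_relationships <- function() {
  tibble::tibble(type = character(), source = character(),
                 target = character(), properties = list())
}

new_property_graph <- function(nodes = empty_nodes(),
                               relationships = empty_relationships()) {
  g <- list(nodes = nodes, relationships = relationships)
  class(g) <- c("property_graph", "list")
  validate_property_graph(g)
}

#' Construct an empty property graph
#'
#' @return A `property_graph` with no nodes or relationships.
#' @export
property_graph <- function() {
  new_property_graph()
}

validate_property_graph <- function(g) {
  if (anyDuplicated(g$nodes$key)) {
    abort("Duplicate node keys in property graph.",
          class = "sbmlgraph_graph_error")
  }
  dangling <- setdiff(c(g$relationships$source, g$relationships$target),
                      g$nodes$key)
  if (length(dangling) > 0L) {
    abort(paste0("Relationship endpoint(s) missing from graph: ",
                 paste(utils::head(gsub("\u001f", ":", dangling), 5L),
                       collapse = ", ")),
          class = "sbmlgraph_graph_error")
  }
  g
}

#' Insert or merge a node
#'
#' Inserts when the key (primary label, id, tag) is absent; otherwise the
#' property maps are unioned with incoming values winning on conflict
#' (conflicts are reported via a message-level condition). Re-upserting an
#' identical node is a no-op.
#'
#' @param graph A `property_graph`.
#' @param node One-row node tibble (as produced by [extract_nodes()]), or a
#'   list with fields `label`, `id`, `tag`, and optionally `labels`,
#'   `properties`.
#' @return The updated `property_graph`.
#' @export
upsert_node <- function(graph, node) {
  stopifnot(inherits(graph, "property_graph"))
  node <- as_node_row(node)
  i <- match(node$key, graph$nodes$key)
  if (is.na(i)) {
    graph$nodes <- dplyr::bind_rows(graph$nodes, node)
    return(graph)
  }
  if (!identical(graph$nodes$label[[i]], node$label)) {
    abort(paste0("Key '", gsub("\u001f", ":", node$key),
                 "' already exists with primary label '",
                 graph$nodes$label[[i]], "'."),
          class = "sbmlgraph_graph_error")
  }
  merged <- merge_properties(graph$nodes$properties[[i]],
                             node$properties[[1]],
                             where = paste0("node ", node$id))
  graph$nodes$properties[[i]] <- merged
  graph$nodes$labels[[i]] <- union(graph$nodes$labels[[i]],
                                   node$labels[[1]])
  graph
}

as_node_row <- function(node) {
  if (is.data.frame(node)) {
    stopifnot(nrow(node) == 1L)
    return(node)
  }
  label <- node$label
  id <- as.character(node$id)
  tag <- as.character(node$tag)
  props <- node$properties %||% list()
  props$id <- id
  props$tag <- tag
  tibble::tibble(key = node_key(label, id, tag), label = label, id = id,
                 tag = tag, labels = list(node$labels %||% label),
                 properties = list(props))
}

merge_properties <- function(old, new, where = "") {
  for (nm in names(new)) {
    if (!is.null(old[[nm]]) && !identical(old[[nm]], new[[nm]])) {
      inform(paste0("Property '", nm, "' overwritten on ", where, "."),
             class = "sbmlgraph_property_conflict")
    }
    old[[nm]] <- new[[nm]]
  }
  old
}

#' Insert or merge a relationship
#'
#' Identity is the (type, source key, target key) triple; an existing edge
#' has its properties merged (incoming wins), a new one is appended. Both
#' endpoints must already be nodes of the graph.
#'
#' @param graph A `property_graph`.
#' @param rel One-row relationship tibble, or a list with `type`, `source`,
#'   `target` (node keys) and optional `properties`.
#' @return The updated `property_graph`.
#' @export
upsert_relationship <- function(graph, rel) {
  stopifnot(inherits(graph, "property_graph"))
  if (is.data.frame(rel)) {
    stopifnot(nrow(rel) == 1L)
    rel <- list(type = rel$type, source = rel$source, target = rel$target,
                properties = rel$properties[[1]])
  }
  missing <- setdiff(c(rel$source, rel$target), graph$nodes$key)
  if (length(missing) > 0L) {
    abort(paste0("Dangling endpoint(s): ",
                 paste(gsub("\u001f", ":", missing), collapse = ", ")),
          class = "sbmlgraph_graph_error")
  }
  i <- which(graph$relationships$type == rel$type &
             graph$relationships$source == rel$source &
             graph$relationships$target == rel$target)
  if (length(i) == 0L) {
    graph$relationships <- dplyr::bind_rows(
      graph$relationships,
      tibble::tibble(type = rel$type, source = rel$source,
                     target = rel$target,
                     properties = list(rel$properties %||% list())))
  } else {
    graph$relationships$properties[[i[[1]]]] <- merge_properties(
      graph$relationships$properties[[i[[1]]]], rel$properties %||% list(),
      where = paste0("edge ", rel$type))
  }
  graph
}

#' Merge one property graph into another
#'
#' Upserts every node then every relationship of `incoming` into `graph`;
#' merging a graph into itself leaves it unchanged.
#'
#' @param graph,incoming `property_graph` objects.
#' @return The merged `property_graph`.
#' @export
merge_graphs <- function(graph, incoming) {
  for (i in seq_len(nrow(incoming$nodes))) {
    graph <- upsert_node(graph, incoming$nodes[i, ])
  }
  for (i in seq_len(nrow(incoming$relationships))) {
    graph <- upsert_relationship(graph, incoming$relationships[i, ])
  }
  graph
}

#' Node and relationship counts per label and type
#'
#' The layout mirrors the usual summary table of an imported model: one row
#' per node label and per relationship type.
#'
#' @param graph A `property_graph`.
#' @return A tibble with columns `element` (`"node"` or `"relationship"`),
#'   `name` (label or type) and `n`.
#' @export
graph_stats <- function(graph) {
  stopifnot(inherits(graph, "property_graph"))
  nodes <- graph$nodes |>
    dplyr::count(name = "n", .data$label) |>
    dplyr::rename(name = "label") |>
    dplyr::mutate(element = "node", .before = 1)
  rels <- graph$relationships |>
    dplyr::count(name = "n", .data$type) |>
    dplyr::rename(name = "type") |>
    dplyr::mutate(element = "relationship", .before = 1)
  dplyr::bind_rows(nodes, rels) |>
    dplyr::arrange(.data$element, .data$name)
}

stats_lookup <- function(stats, element, name) {
  n <- stats$n[stats$element == element & stats$name == name]
  if (length(n) == 0L) 0L else n[[1]]
}

#' Degree of a node
#'
#' @param graph A `property_graph`.
#' @param key A node key (from `graph$nodes$key`).
#' @param type Optional relationship type filter.
#' @param direction `"all"` (default), `"out"` or `"in"`.
#' @return Integer count of incident edges.
#' @export
node_degree <- function(graph, key, type = NULL,
                        direction = c("all", "out", "in")) {
  stopifnot(inherits(graph, "property_graph"))
  direction <- match.arg(direction)
  if (!(key %in% graph$nodes$key)) {
    abort("Unknown node key.", class = "sbmlgraph_graph_error")
  }
  r <- graph$relationships
  if (!is.null(type)) r <- r[r$type %in% type, ]
  out_n <- sum(r$source == key)
  in_n <- sum(r$target == key)
  switch(direction, all = out_n + in_n, out = out_n, `in` = in_n)
}

#' Find node keys by label and/or id
#'
#' @param graph A `property_graph`.
#' @param label Optional primary-label filter.
#' @param id Optional component-id filter.
#' @param tag Optional tag filter.
#' @return Character vector of matching node keys.
#' @export
find_nodes <- function(graph, label = NULL, id = NULL, tag = NULL) {
  n <- graph$nodes
  if (!is.null(label)) n <- n[n$label %in% label, ]
  if (!is.null(id)) n <- n[n$id %in% id, ]
  if (!is.null(tag)) n <- n[n$tag %in% tag, ]
  n$key
}

#' @export
print.property_graph <- function(x, ...) {
  cat("<property_graph> ", nrow(x$nodes), " node(s), ",
      nrow(x$relationships), " relationship(s)\n", sep = "")
  s <- graph_stats(x)
  if (nrow(s)) print(s, n = 20)
  invisible(x)
}

#' Tidy a property graph into node or relationship tables
#'
#' @param x A `property_graph`.
#' @param what `"nodes"` (default), `"relationships"` or `"stats"`.
#' @param ... Unused.
#' @return A tibble. Nodes come back one row per node with `label`, `id`,
#'   `tag` and a `properties` list-column; relationships with endpoint
#'   labels/ids unpacked from the keys.
#' @export
tidy.property_graph <- function(x, what = c("nodes", "relationships",
                                            "stats"), ...) {
  what <- match.arg(what)
  if (what == "nodes") {
    return(dplyr::select(x$nodes, -"key"))
  }
  if (what == "stats") return(graph_stats(x))
  split_key <- function(k, field) {
    purrr::map_chr(strsplit(k, "\u001f", fixed = TRUE), field)
  }
  tibble::tibble(
    type = x$relationships$type,
    source_label = split_key(x$relationships$source, 1),
    source_id = split_key(x$relationships$source, 2),
    target_label = split_key(x$relationships$target, 1),
    target_id = split_key(x$relationships$target, 2),
    tag = split_key(x$relationships$source, 3),
    properties = x$relationships$properties
  )
}

#' One-row summary of a property graph
#'
#' @param x A `property_graph`.
#' @param ... Unused.
#' @return A tibble with node/relationship totals and distinct label, type
#'   and tag counts.
#' @export
glance.property_graph <- function(x, ...) {
  tibble::tibble(
    n_nodes = nrow(x$nodes),
    n_relationships = nrow(x$relationships),
    n_labels = dplyr::n_distinct(x$nodes$label),
    n_types = dplyr::n_distinct(x$relationships$type),
    n_tags = dplyr::n_distinct(x$nodes$tag)
  )
}

#' Bar chart of graph composition
#'
#' Plots the per-label node counts and per-type relationship counts of a
#' graph, faceted by element kind — the at-a-glance version of
#' [graph_stats()].
#'
#' @param object A `property_graph`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.property_graph <- function(object, ...) {
  s <- graph_stats(object)
  ggplot(s, aes(x = stats::reorder(.data$name, .data$n), y = .data$n)) +
    geom_col() +
    coord_flip() +
    facet_wrap(~ .data$element, scales = "free") +
    labs(x = NULL, y = "count", title = "Property graph composition")
}
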