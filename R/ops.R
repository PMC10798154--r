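# Analysis operations on an imported metabolic graph: neighborhood viewing,
# dense-node flagging, fixed-length producer paths, species-reference
# contraction and degree-based pruning. Path search is delegated to igraph;
# everything else is straight table manipulation.

graph_to_igraph <- function(graph, directed = TRUE) {
  if (nrow(graph$nodes) == 0L) {
    return(igraph::make_empty_graph(n = 0, directed = directed))
  }
  edges <- graph$relationships
  igraph::graph_from_data_frame(
    d = data.frame(from = edges$source, to = edges$target,
                   type = edges$type, stringsAsFactors = FALSE),
    directed = directed,
    vertices = data.frame(name = graph$nodes$key, stringsAsFactors = FALSE))
}

subgraph_by_keys <- function(graph, keys) {
  nodes <- graph$nodes[graph$nodes$key %in% keys, ]
  rels <- graph$relationships[graph$relationships$source %in% keys &
                              graph$relationships$target %in% keys, ]
  new_property_graph(nodes, rels)
}

node_property <- function(graph, key, name) {
  i <- match(key, graph$nodes$key)
  if (is.na(i)) return(NULL)
  graph$nodes$properties[[i]][[name]]
}

#' Neighborhood of a named species
#'
#' Returns the subgraph induced by all nodes within `radius` hops
#' (directions ignored) of every Species node whose `name` property equals
#' `species_name` exactly, together with the edges among them — the typical
#' "show me this metabolite and its reactions" view.
#'
#' @param graph A `property_graph`.
#' @param species_name Exact `name` property value to match (falls back to
#'   the `id` when a species has no name property).
#' @param radius Hop count, at least 1.
#' @param label Primary label of species nodes (default `"Species"`).
#' @return A `property_graph`; empty when no species matches.
#' @export
species_neighborhood <- function(graph, species_name, radius = 1L,
                                 label = "Species") {
  stopifnot(inherits(graph, "property_graph"), radius >= 1L)
  seeds <- graph$nodes$key[
    graph$nodes$label == label &
      purrr::map_lgl(graph$nodes$properties, function(p)
        identical(p$name %||% p$id, species_name))]
  if (length(seeds) == 0L) return(property_graph())
  ig <- graph_to_igraph(graph, directed = FALSE)
  hoods <- igraph::ego(ig, order = radius,
                       nodes = match(seeds, igraph::V(ig)$name))
  keys <- unique(unlist(purrr::map(hoods, function(h) names(h))))
  subgraph_by_keys(graph, keys)
}

#' Flag high-degree nodes
#'
#' Marks every node carrying `label` whose total degree is at least
#' `threshold` with a boolean `dense = TRUE` property; other nodes are left
#' untouched. Used to exclude hub ("currency") metabolites from path
#' queries.
#'
#' @param graph A `property_graph`.
#' @param label Primary label to consider.
#' @param threshold Minimum degree (>= 0).
#' @return The updated `property_graph`.
#' @export
flag_dense_nodes <- function(graph, label, threshold) {
  stopifnot(inherits(graph, "property_graph"), threshold >= 0)
  deg <- table(c(graph$relationships$source, graph$relationships$target))
  for (i in which(graph$nodes$label == label)) {
    k <- graph$nodes$key[[i]]
    d <- if (k %in% names(deg)) deg[[k]] else 0L
    if (d >= threshold) graph$nodes$properties[[i]]$dense <- TRUE
  }
  graph
}

#' Species producing a target through a fixed number of reactions
#'
#' Enumerates simple (node-disjoint) paths that end at the target species
#' and traverse exactly `n_reactions` Reaction nodes, alternating
#' species/reaction, with the starting species located in the named
#' compartment. Traversal follows the biochemical direction: a species
#' enters a reaction it is a reactant of, and a reaction leads to its
#' products. With the bundled schemas those facts are stored as
#' `IS_REACTANT` and `HAS_PRODUCT` edges from the Reaction node, so stored
#' edge orientation is interpreted per type rather than taken literally; set
#' `reactant_types`/`product_types` for schemas drawn with other type names.
#'
#' @param graph A `property_graph`.
#' @param target_species_name Exact `name` (or `id`) of the produced
#'   species.
#' @param source_compartment Compartment id that starting species must lie
#'   in (via their `compartment` property or an `IN_COMPARTMENT`-style
#'   edge). Unknown compartments yield an empty result.
#' @param n_reactions Number of reaction steps, at least 1.
#' @param reactant_types,product_types Relationship types encoding
#'   species-is-reactant-of and reaction-produces facts.
#' @return A tibble of paths: `source_id`, `target_id`, `n_reactions` and a
#'   `path` list-column of alternating node keys and relationship types.
#' @export
producers_at_distance <- function(graph, target_species_name,
                                  source_compartment, n_reactions = 2L,
                                  reactant_types = c("IS_REACTANT",
                                                     "HAS_REACTANT"),
                                  product_types = c("HAS_PRODUCT",
                                                    "IS_PRODUCT")) {
  stopifnot(inherits(graph, "property_graph"), n_reactions >= 1L)
  labels <- setNames(graph$nodes$label, graph$nodes$key)

  # semantic digraph: species -> reaction (reactant), reaction -> species
  # (product), whichever way the schema stored the edge
  orient <- function(rel_row) {
    s <- rel_row$source; t <- rel_row$target
    if (rel_row$type %in% reactant_types) {
      if (labels[[s]] == "Reaction") c(t, s) else c(s, t)
    } else {
      if (labels[[s]] == "Reaction") c(s, t) else c(t, s)
    }
  }
  rel <- graph$relationships[
    graph$relationships$type %in% c(reactant_types, product_types), ]
  if (nrow(rel) == 0L) return(empty_path_result())
  oriented <- purrr::map(seq_len(nrow(rel)), function(i)
    orient(as.list(rel[i, c("type", "source", "target")])))
  edge_df <- data.frame(from = purrr::map_chr(oriented, 1),
                        to = purrr::map_chr(oriented, 2),
                        type = rel$type, stringsAsFactors = FALSE)
  edge_df <- edge_df[!duplicated(edge_df[, c("from", "to", "type")]), ]

  targets <- graph$nodes$key[
    graph$nodes$label == "Species" &
      purrr::map_lgl(graph$nodes$properties, function(p)
        identical(p$name %||% p$id, target_species_name))]
  sources <- species_in_compartment(graph, source_compartment)
  sources <- setdiff(sources, targets)
  if (length(targets) == 0L || length(sources) == 0L) {
    return(empty_path_result())
  }

  verts <- unique(c(edge_df$from, edge_df$to, targets, sources))
  ig <- igraph::graph_from_data_frame(edge_df, directed = TRUE,
                                      vertices = data.frame(name = verts))
  want_len <- 2L * as.integer(n_reactions)
  out <- list()
  for (src in sources) {
    paths <- igraph::all_simple_paths(ig, from = src,
                                      to = intersect(targets,
                                                     igraph::V(ig)$name),
                                      mode = "out", cutoff = want_len)
    for (p in paths) {
      keys <- names(p)
      if (length(keys) != want_len + 1L) next
      out[[length(out) + 1L]] <- tibble::tibble(
        source_id = key_parts(keys[[1]])$id,
        target_id = key_parts(keys[[length(keys)]])$id,
        n_reactions = as.integer(n_reactions),
        path = list(interleave_path(keys, edge_df)))
    }
  }
  if (length(out) == 0L) return(empty_path_result())
  dplyr::bind_rows(out)
}

empty_path_result <- function() {
  tibble::tibble(source_id = character(), target_id = character(),
                 n_reactions = integer(), path = list())
}

interleave_path <- function(keys, edge_df) {
  steps <- character(2L * length(keys) - 1L)
  steps[seq(1L, length(steps), by = 2L)] <- keys
  for (i in seq_len(length(keys) - 1L)) {
    hit <- edge_df$type[edge_df$from == keys[[i]] &
                        edge_df$to == keys[[i + 1L]]]
    steps[[2L * i]] <- hit[[1]]
  }
  steps
}

species_in_compartment <- function(graph, compartment_id) {
  by_prop <- graph$nodes$key[
    graph$nodes$label == "Species" &
      purrr::map_lgl(graph$nodes$properties, function(p)
        identical(p$compartment, compartment_id))]
  comp_keys <- graph$nodes$key[graph$nodes$label == "Compartment" &
                               graph$nodes$id == compartment_id]
  rel <- graph$relationships
  touching <- c(rel$source[rel$target %in% comp_keys],
                rel$target[rel$source %in% comp_keys])
  by_edge <- intersect(touching,
                       graph$nodes$key[graph$nodes$label == "Species"])
  unique(c(by_prop, by_edge))
}

#' Contract SpeciesReference nodes into their Species
#'
#' Graph refactoring for pathway analysis: every SpeciesReference node is
#' removed and its edges re-attached to the Species it references (through
#' its `species` property, within the same tag), preserving edge types and
#' collapsing the duplicates this creates. Self-loops produced by the
#' reference edge itself are dropped, as are SpeciesReference nodes whose
#' species cannot be resolved (with a warning).
#'
#' @param graph A `property_graph`.
#' @return The refactored `property_graph`. Species and Reaction node counts
#'   are conserved; the edge count never increases.
#' @export
contract_species_references <- function(graph) {
  stopifnot(inherits(graph, "property_graph"))
  is_ref <- normalize_name(ifelse(nzchar(graph$nodes$label),
                                  graph$nodes$label, "x")) == "speciesreference"
  if (!any(is_ref)) return(graph)
  remap <- character()
  drop_keys <- character()
  for (i in which(is_ref)) {
    key <- graph$nodes$key[[i]]
    sp <- graph$nodes$properties[[i]]$species
    target <- if (!is.null(sp)) {
      find_nodes(graph, label = "Species", id = as.character(sp),
                 tag = graph$nodes$tag[[i]])
    } else character()
    if (length(target) == 0L) {
      warn(paste0("SpeciesReference '", graph$nodes$id[[i]],
                  "' resolves to no Species; node dropped."),
           class = "sbmlgraph_unresolved_reference")
      drop_keys <- c(drop_keys, key)
    } else {
      remap[[key]] <- target[[1]]
    }
  }
  rels <- graph$relationships
  keep <- !(rels$source %in% drop_keys | rels$target %in% drop_keys)
  rels <- rels[keep, ]
  rels$source <- ifelse(rels$source %in% names(remap),
                        remap[rels$source], rels$source)
  rels$target <- ifelse(rels$target %in% names(remap),
                        remap[rels$target], rels$target)
  rels <- rels[rels$source != rels$target, ]
  rels <- dplyr::distinct(rels, .data$type, .data$source, .data$target,
                          .keep_all = TRUE)
  nodes <- graph$nodes[!is_ref, ]
  new_property_graph(nodes, rels)
}

#' Remove low-connectivity species
#'
#' Deletes every Species node adjacent to fewer than `min_reactions`
#' distinct Reaction nodes, along with its incident edges. Applied once —
#' species whose reaction count drops below the threshold because a
#' neighbor was removed are not cascaded.
#'
#' @param graph A `property_graph`.
#' @param min_reactions Minimum number of distinct adjacent reactions
#'   (>= 0; 0 removes nothing).
#' @return The pruned `property_graph`.
#' @export
prune_species_by_degree <- function(graph, min_reactions) {
  stopifnot(inherits(graph, "property_graph"), min_reactions >= 0)
  if (min_reactions == 0) return(graph)
  labels <- setNames(graph$nodes$label, graph$nodes$key)
  rels <- graph$relationships
  neighbor_pairs <- dplyr::bind_rows(
    tibble::tibble(a = rels$source, b = rels$target),
    tibble::tibble(a = rels$target, b = rels$source))
  reaction_neighbors <- neighbor_pairs |>
    dplyr::filter(labels[.data$b] == "Reaction") |>
    dplyr::distinct(.data$a, .data$b) |>
    dplyr::count(.data$a, name = "n_reactions")
  counts <- setNames(reaction_neighbors$n_reactions, reaction_neighbors$a)
  species_keys <- graph$nodes$key[graph$nodes$label == "Species"]
  doomed <- species_keys[
    purrr::map_int(species_keys, function(k)
      as.integer(counts[k] %||% 0L) %|na|% 0L) < min_reactions]
  nodes <- graph$nodes[!(graph$nodes$key %in% doomed), ]
  rels <- rels[!(rels$source %in% doomed | rels$target %in% doomed), ]
  new_property_graph(nodes, rels)
}

`%|na|%` <- function(x, y) ifelse(is.na(x), y, x)
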