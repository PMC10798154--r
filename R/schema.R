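#' Load a graph schema from an Arrows export
#'
#' The schema that drives extraction is drawn in the Arrows web application
#' and exported as a JSON document with top-level `nodes` and `relationships`
#' collections. Each node carries an `id` (schema-local key), a stack of
#' `labels` and a `properties` map; each relationship carries a `type`,
#' `fromId`/`toId` endpoint keys and an optional `properties` map. Positional
#' and styling fields (`position`, `caption`, `style`) are discarded.
#'
#' By convention the first label of a schema node names the SBML component to
#' extract (`Species`, `Reaction`, `unitDefinition`, ...); any further labels
#' are carried verbatim onto the produced graph nodes. Property values in the
#' export are optional type annotations and are kept for documentation only.
#' Relationship direction is meaningful: edges are created source to target as
#' drawn.
#'
#' @param schema_text Arrows export document text (JSON), or a path to a file
#'   containing it.
#' @return An `sbml_schema` object: a list with tibbles `nodes`
#'   (`key`, `labels` list-column, `properties` list-column) and
#'   `relationships` (`type`, `source_key`, `target_key`, `properties`).
#' @examples
#' sch <- load_schema(example_schema("metabolic"))
#' sch$nodes
#' @export
load_schema <- function(schema_text) {
  txt <- read_text_arg(schema_text)
  doc <- tryCatch(
    jsonlite::fromJSON(txt, simplifyVector = FALSE),
    error = function(e) {
      abort(paste0("Malformed Arrows export: ", conditionMessage(e)),
            class = "sbmlgraph_parse_error")
    }
  )
  if (!is.list(doc)) {
    abort("Malformed Arrows export: top level is not an object.",
          class = "sbmlgraph_parse_error")
  }
  raw_nodes <- doc$nodes %||% list()
  raw_rels <- doc$relationships %||% list()

  nodes <- purrr::map(raw_nodes, function(nd) {
    key <- as.character(nd$id %||% abort(
      "Malformed Arrows export: node without `id`.",
      class = "sbmlgraph_parse_error"))
    labels <- as.character(unlist(nd$labels %||% character()))
    if (length(labels) == 0L || any(!nzchar(labels)) ||
        any(grepl("\\s", labels))) {
      abort(paste0("Schema node '", key, "' needs at least one ",
                   "whitespace-free label."),
            class = "sbmlgraph_schema_error")
    }
    props <- nd$properties %||% list()
    props <- setNames(as.list(vapply(props, function(p)
      as.character(p %||% "")[1], character(1))), names(props))
    if (anyDuplicated(names(props))) {
      abort(paste0("Schema node '", key, "' has duplicated property names."),
            class = "sbmlgraph_schema_error")
    }
    list(key = key, labels = labels, properties = props)
  })
  keys <- purrr::map_chr(nodes, "key")
  if (anyDuplicated(keys)) {
    abort(paste0("Duplicated schema node keys: ",
                 paste(unique(keys[duplicated(keys)]), collapse = ", ")),
          class = "sbmlgraph_schema_error")
  }

  rels <- purrr::map(raw_rels, function(rl) {
    type <- as.character(rl$type %||% "")
    if (!nzchar(type)) {
      abort("Malformed Arrows export: relationship without `type`.",
            class = "sbmlgraph_parse_error")
    }
    props <- rl$properties %||% list()
    props <- setNames(as.list(vapply(props, function(p)
      as.character(p %||% "")[1], character(1))), names(props))
    list(type = type,
         source_key = as.character(rl$fromId %||% ""),
         target_key = as.character(rl$toId %||% ""),
         properties = props)
  })
  dangling <- unique(unlist(purrr::map(rels, function(rl)
    setdiff(c(rl$source_key, rl$target_key), keys))))
  if (length(dangling) > 0L) {
    abort(paste0("Schema relationships reference missing node keys: ",
                 paste(dangling, collapse = ", ")),
          class = "sbmlgraph_schema_error")
  }

  schema <- list(
    nodes = tibble::tibble(
      key = keys,
      labels = purrr::map(nodes, "labels"),
      properties = purrr::map(nodes, "properties")
    ),
    relationships = tibble::tibble(
      type = purrr::map_chr(rels, "type"),
      source_key = purrr::map_chr(rels, "source_key"),
      target_key = purrr::map_chr(rels, "target_key"),
      properties = purrr::map(rels, "properties")
    )
  )
  structure(schema, class = c("sbml_schema", "list"))
}

#' Serialize a schema back to the Arrows export format
#'
#' Inverse of [load_schema()] up to the discarded visual fields; round-tripping
#' preserves labels, property names and relationship types field by field.
#'
#' @param schema An `sbml_schema`.
#' @return A JSON document string.
#' @export
write_schema <- function(schema) {
  stopifnot(inherits(schema, "sbml_schema"))
  nodes <- purrr::pmap(schema$nodes, function(key, labels, properties) {
    list(id = key, labels = as.list(labels), properties = properties,
         position = list(x = 0, y = 0))
  })
  rels <- purrr::pmap(schema$relationships,
                      function(type, source_key, target_key, properties) {
    list(id = paste0("r", source_key, target_key, type), type = type,
         fromId = source_key, toId = target_key, properties = properties)
  })
  jsonlite::toJSON(list(nodes = nodes, relationships = rels),
                   auto_unbox = TRUE, pretty = TRUE)
}

#' Check a schema against a parsed document's component catalog
#'
#' Extraction silently yields zero nodes for a schema label that names no
#' component kind in the document, and omits properties naming no attribute;
#' this pre-flight reports those mismatches as diagnostics so typos
#' (`Specie` for `Species`) surface before an import.
#'
#' @param schema An `sbml_schema`.
#' @param catalog A component catalog from [component_catalog()], or an
#'   `sbml_document` (its catalog is computed).
#' @param doc Optionally the `sbml_document` itself, used to check declared
#'   properties against attributes actually present on instances.
#' @return A tibble of diagnostics (`severity`, `kind`, `label`, `property`,
#'   `message`); zero rows means the schema is fully matched.
#' @export
validate_schema <- function(schema, catalog, doc = NULL) {
  stopifnot(inherits(schema, "sbml_schema"))
  if (inherits(catalog, "sbml_document")) {
    doc <- doc %||% catalog
    catalog <- component_catalog(catalog)
  }
  known <- unique(catalog$kind_norm)
  diags <- list()
  for (i in seq_len(nrow(schema$nodes))) {
    labels <- schema$nodes$labels[[i]]
    primary <- labels[[1]]
    if (!(normalize_name(primary) %in% known)) {
      diags[[length(diags) + 1L]] <- tibble::tibble(
        severity = "warning", kind = "unknown_label", label = primary,
        property = NA_character_,
        message = paste0("Schema label '", primary,
                         "' matches no component kind in the document."))
      next
    }
    if (is.null(doc)) next
    recs <- records_of_kind(doc, primary)
    seen <- unique(unlist(purrr::map(recs, function(r) {
      c(names(r$attributes),
        if (!is.null(r$math)) "math",
        if (!is.null(r$annotation)) "annotation",
        if (!is.null(r$notes)) "notes")
    })))
    seen_norm <- if (length(seen)) normalize_name(seen) else character()
    for (p in names(schema$nodes$properties[[i]])) {
      if (!(normalize_name(p) %in% seen_norm)) {
        diags[[length(diags) + 1L]] <- tibble::tibble(
          severity = "warning", kind = "unknown_property", label = primary,
          property = p,
          message = paste0("Property '", p, "' matches no attribute on any '",
                           primary, "' instance."))
      }
    }
  }
  if (length(diags) == 0L) {
    return(tibble::tibble(severity = character(), kind = character(),
                          label = character(), property = character(),
                          message = character()))
  }
  dplyr::bind_rows(diags)
}

#' Bundled example schemas
#'
#' Two ready-made Arrows exports ship with the package: `"metabolic"` selects
#' the metabolite/reaction/compartment core of a model (species linked to
#' their compartment, reactions to their reactants and products), and `"gem"`
#' extends it with the model header, parameters, unit definitions and fbc
#' gene products (flux bounds, gene-reaction links) as used for genome-scale
#' models.
#'
#' @param name `"metabolic"` or `"gem"`.
#' @return Path to the bundled schema JSON file.
#' @examples
#' load_schema(example_schema("gem"))
#' @export
example_schema <- function(name = c("metabolic", "gem")) {
  name <- match.arg(name)
  system.file("extdata", paste0("schema_", name, ".json"),
              package = "sbmlgraph", mustWork = TRUE)
}

#' @export
print.sbml_schema <- function(x, ...) {
  cat("<sbml_schema> ", nrow(x$nodes), " node(s), ",
      nrow(x$relationships), " relationship(s)\n", sep = "")
  if (nrow(x$nodes)) {
    cat("labels:", paste(purrr::map_chr(x$nodes$labels, 1), collapse = ", "),
        "\n")
  }
  if (nrow(x$relationships)) {
    cat("types: ", paste(x$relationships$type, collapse = ", "), "\n")
  }
  invisible(x)
}

# Accepts literal document text or a file path.
read_text_arg <- function(x) {
  stopifnot(is.character(x), length(x) >= 1L)
  if (length(x) == 1L && !grepl("[<{\n]", x) && file.exists(x)) {
    return(paste(readLines(x, warn = FALSE), collapse = "\n"))
  }
  paste(x, collapse = "\n")
}
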