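# SBML parsing: the document is flattened into a uniform pre-order list of
# component records (kind, package, id, attributes, math/annotation/notes,
# path) that the mapper introspects. No libsbml-style object model is needed:
# name matching operates on tag and attribute names as they appear in the XML.

SBML_PACKAGE_URIS <- c(
  fbc    = "/fbc/",
  groups = "/groups/",
  layout = "/layout/",
  qual   = "/qual/"
)

# Attributes declared numeric or boolean by the SBML core and package specs
# are coerced; everything else stays a string. Unparseable declared-numeric
# values are kept as strings with a warning rather than failing the import.
NUMERIC_ATTRS <- c(
  "stoichiometry", "size", "value", "initialAmount", "initialConcentration",
  "spatialDimensions", "multiplier", "exponent", "scale", "offset",
  "charge", "width", "height", "depth", "x", "y", "z",
  "maxLevel", "initialLevel", "resultLevel", "thresholdLevel", "outputLevel"
)
BOOLEAN_ATTRS <- c(
  "constant", "reversible", "fast", "boundaryCondition",
  "hasOnlySubstanceUnits", "useValuesFromTriggerTime", "persistent",
  "initialValue", "required", "strict"
)

#' Parse an SBML document into a component-record model
#'
#' Every element beneath `<model>` becomes a component record exposing its
#' kind (the tag name), package (`core`, or `fbc`/`groups`/`layout`/`qual` for
#' elements in those Level 3 package namespaces), identifier, attribute map
#' and a document path that uniquely and deterministically addresses it.
#' `listOf*` containers are retained as records of their own. MathML children
#' are serialized to an infix formula string; `annotation` and `notes`
#' subtrees are kept as raw XML text.
#'
#' Supports SBML Level 2 Version 5 and Level 3 Version 2 core. Elements in an
#' unrecognized package namespace are still recorded, with a package label
#' derived from their namespace prefix and a warning.
#'
#' @param xml_text SBML document text, or a path to an `.xml` file.
#' @return An `sbml_document`: list with `level`, `version`, `records`
#'   (pre-order list of component records; the first is the `model` record)
#'   and lookup vectors `paths`, `kinds_norm`.
#' @examples
#' doc <- parse_document(generate_model(fixture_spec()))
#' component_catalog(doc)
#' @export
parse_document <- function(xml_text) {
  txt <- read_text_arg(xml_text)
  xml <- tryCatch(
    xml2::read_xml(txt),
    error = function(e) {
      abort(paste0("Malformed XML: ", conditionMessage(e)),
            class = "sbmlgraph_parse_error")
    }
  )
  if (xml2::xml_name(xml) != "sbml") {
    abort(paste0("Not an SBML document: root element is <",
                 xml2::xml_name(xml), ">."),
          class = "sbmlgraph_format_error")
  }
  level <- suppressWarnings(as.integer(xml2::xml_attr(xml, "level")))
  version <- suppressWarnings(as.integer(xml2::xml_attr(xml, "version")))
  ns_map <- xml2::xml_ns(xml)

  model <- xml2::xml_find_first(xml, "./*[local-name()='model']")
  if (inherits(model, "xml_missing")) {
    abort("SBML document has no <model> element.",
          class = "sbmlgraph_format_error")
  }

  env <- new.env(parent = emptyenv())
  env$records <- vector("list", 256L)
  env$n <- 0L
  env$unknown_ns <- character()

  walk <- function(el, parent_idx, path) {
    info <- element_package(el, ns_map, env)
    attrs <- collect_attributes(el)
    rec <- list(
      idx = NA_integer_, kind = xml2::xml_name(el), package = info,
      id = attrs$id %||% NULL, attributes = attrs$values,
      math = NULL, annotation = NULL, notes = NULL,
      path = path, spath = NA_character_,
      parent = parent_idx, children = integer()
    )
    env$n <- env$n + 1L
    idx <- env$n
    rec$idx <- idx
    if (idx > length(env$records)) {
      length(env$records) <- 2L * length(env$records)
    }
    env$records[[idx]] <- rec

    counters <- list()
    child_idx <- integer()
    for (ch in xml2::xml_children(el)) {
      nm <- xml2::xml_name(ch)
      if (nm == "math") {
        env$records[[idx]]$math <- mathml_to_infix(ch)
      } else if (nm == "annotation") {
        env$records[[idx]]$annotation <- as.character(ch)
      } else if (nm == "notes") {
        env$records[[idx]]$notes <- as.character(ch)
      } else {
        ord <- counters[[nm]] %||% 0L
        counters[[nm]] <- ord + 1L
        ci <- walk(ch, idx, paste0(path, "/", nm, "[", ord, "]"))
        child_idx <- c(child_idx, ci)
      }
    }
    env$records[[idx]]$children <- child_idx
    idx
  }
  walk(model, NA_integer_, "model")
  records <- env$records[seq_len(env$n)]

  if (length(env$unknown_ns) > 0L) {
    warn(paste0("Unsupported package namespace(s): ",
                paste(unique(env$unknown_ns), collapse = ", "),
                "; elements recorded with their prefix as package label."),
         class = "sbmlgraph_unknown_package")
  }

  records <- assign_surrogate_paths(records)

  doc <- list(
    level = level, version = version,
    records = records,
    paths = purrr::map_chr(records, "path"),
    kinds_norm = normalize_name(purrr::map_chr(records, "kind"))
  )
  class(doc) <- c("sbml_document", "list")
  warn_duplicate_ids(doc)
  doc
}

element_package <- function(el, ns_map, env) {
  qualified <- xml2::xml_name(el, ns_map)
  if (!grepl(":", qualified, fixed = TRUE)) return("core")
  prefix <- sub(":.*$", "", qualified)
  uri <- unname(ns_map[prefix])
  if (is.na(uri)) return("core")
  # core namespaces: .../sbml/levelN/versionM with an optional /core suffix
  if (grepl("sbml\\.org/sbml/level\\d+(/version\\d+)?(/core)?/?$", uri)) {
    return("core")
  }
  for (pkg in names(SBML_PACKAGE_URIS)) {
    if (grepl(SBML_PACKAGE_URIS[[pkg]], uri, fixed = TRUE)) return(pkg)
  }
  env$unknown_ns <- c(env$unknown_ns, prefix)
  prefix
}

collect_attributes <- function(el) {
  raw <- xml2::xml_attrs(el)
  values <- list()
  for (nm in names(raw)) {
    local <- sub("^.*:", "", nm)
    if (local %in% c("xmlns", "schemaLocation")) next
    has_prefix <- grepl(":", nm, fixed = TRUE)
    if (!is.null(values[[local]]) && has_prefix) next  # core name wins
    values[[local]] <- coerce_attribute(local, raw[[nm]])
  }
  id <- values[["id"]]
  list(values = values, id = if (!is.null(id)) as.character(id) else NULL)
}

coerce_attribute <- function(name, value) {
  if (name %in% BOOLEAN_ATTRS) {
    if (value %in% c("true", "1")) return(TRUE)
    if (value %in% c("false", "0")) return(FALSE)
    return(value)
  }
  if (name %in% NUMERIC_ATTRS) {
    num <- suppressWarnings(as.numeric(value))
    if (is.na(num) && !identical(toupper(value), "NAN")) {
      warn(paste0("Attribute '", name, "' declared numeric but value '",
                  value, "' is not parseable; kept as string."),
           class = "sbmlgraph_coercion_warning")
      return(value)
    }
    return(num)
  }
  value
}

# Surrogate document paths skip listOf* wrappers and the model root, so the
# first eventAssignment of the first event reads "event[0]/eventAssignment[0]".
# They are the stable fallback identifiers for id-less components.
assign_surrogate_paths <- function(records) {
  counters <- new.env(parent = emptyenv())
  for (i in seq_along(records)) {
    rec <- records[[i]]
    if (i == 1L) {
      records[[i]]$spath <- "model"
      next
    }
    p <- rec$parent
    while (!is.na(p) && p != 1L && is_listof(records[[p]]$kind)) {
      p <- records[[p]]$parent
    }
    lp <- if (is.na(p) || p == 1L) "" else records[[p]]$spath
    ckey <- paste(lp, rec$kind, sep = "\u001f")
    ord <- get0(ckey, envir = counters, ifnotfound = 0L)
    assign(ckey, ord + 1L, envir = counters)
    seg <- paste0(rec$kind, "[", ord, "]")
    records[[i]]$spath <- if (nzchar(lp)) paste0(lp, "/", seg) else seg
  }
  records
}

warn_duplicate_ids <- function(doc) {
  ids <- purrr::map_chr(doc$records, function(r) r$id %||% NA_character_)
  by_kind <- split(ids, purrr::map_chr(doc$records, "kind"))
  for (kind in names(by_kind)) {
    v <- by_kind[[kind]][!is.na(by_kind[[kind]])]
    dup <- unique(v[duplicated(v)])
    if (length(dup) > 0L) {
      warn(paste0("Duplicated '", kind, "' ids: ",
                  paste(dup, collapse = ", ")),
           class = "sbmlgraph_duplicate_id")
    }
  }
  invisible(doc)
}

#' Tabulate the component kinds present in a document
#'
#' @param doc An `sbml_document`.
#' @return A tibble with one row per component kind: `kind` (as spelled in
#'   the document), `kind_norm` (canonical matching form), `package`, `n`.
#'   Counts cover every record, containers included, so `sum(n)` equals the
#'   total record count.
#' @export
component_catalog <- function(doc) {
  stopifnot(inherits(doc, "sbml_document"))
  tibble::tibble(
    kind = purrr::map_chr(doc$records, "kind"),
    kind_norm = doc$kinds_norm,
    package = purrr::map_chr(doc$records, "package")
  ) |>
    dplyr::count(.data$kind, .data$kind_norm, .data$package, name = "n") |>
    dplyr::arrange(dplyr::desc(.data$n), .data$kind)
}

#' Look up a record attribute by schema property name
#'
#' Matching is canonical (case/punctuation-insensitive): `"sboTerm"` finds
#' the `sboTerm` attribute, a package-qualified attribute such as
#' `fbc:charge` is found under `"charge"`. The pseudo-properties `math`,
#' `annotation` and `notes` return the serialized formula string and the raw
#' XML text respectively.
#'
#' @param record A component record (an element of `doc$records`).
#' @param property_name Property name, non-empty.
#' @return The attribute value (string, number or logical), or `NULL` when
#'   nothing matches.
#' @export
attribute_value <- function(record, property_name) {
  want <- normalize_name(property_name)
  if (want == "math") return(record$math)
  if (want == "annotation") return(record$annotation)
  if (want == "notes") return(record$notes)
  nms <- names(record$attributes)
  if (length(nms) > 0L) {
    hit <- which(normalize_name(nms) == want)
    if (length(hit) > 0L) return(record$attributes[[hit[[1]]]])
  }
  NULL
}

#' All records strictly beneath a record, in document order
#'
#' @param doc An `sbml_document`.
#' @param record A component record or its index in `doc$records`.
#' @return A list of component records (empty for a leaf).
#' @export
descendant_records <- function(doc, record) {
  stopifnot(inherits(doc, "sbml_document"))
  rec <- if (is.numeric(record)) doc$records[[record]] else record
  hits <- startsWith(doc$paths, paste0(rec$path, "/"))
  doc$records[hits]
}

records_of_kind <- function(doc, label) {
  doc$records[doc$kinds_norm == normalize_name(label)]
}

#' @export
print.sbml_document <- function(x, ...) {
  cat("<sbml_document> SBML L", x$level, "V", x$version, ", ",
      length(x$records), " component record(s)\n", sep = "")
  print(component_catalog(x), n = 10)
  invisible(x)
}

# --- MathML serialization -------------------------------------------------

MATHML_INFIX <- c(
  plus = "+", times = "*", divide = "/", power = "^",
  eq = "==", neq = "!=", lt = "<", leq = "<=", gt = ">", geq = ">=",
  and = "&&", or = "||"
)

# Serializes a <math> element to a deterministic infix dialect: single spaces
# around binary operators, nested infix operands parenthesized, named
# functions rendered f(x, y).
mathml_to_infix <- function(math_el) {
  kids <- xml2::xml_children(math_el)
  if (length(kids) == 0L) return("")
  parts <- purrr::map(kids, serialize_math_node)
  paste(purrr::map_chr(parts, "txt"), collapse = "; ")
}

serialize_math_node <- function(node) {
  nm <- xml2::xml_name(node)
  leaf <- function(txt) list(txt = txt, infix = FALSE)
  if (nm %in% c("ci", "csymbol")) {
    return(leaf(trimws(xml2::xml_text(node))))
  }
  if (nm == "cn") {
    pieces <- trimws(strsplit(xml2::xml_text(node), "\\s+")[[1]])
    pieces <- pieces[nzchar(pieces)]
    sep <- xml2::xml_find_first(node, "./*[local-name()='sep']")
    if (!inherits(sep, "xml_missing") && length(pieces) == 2L) {
      return(leaf(paste0(pieces[[1]], "e", pieces[[2]])))
    }
    return(leaf(paste(pieces, collapse = "")))
  }
  if (nm %in% c("true", "false", "pi", "infinity", "notanumber")) {
    return(leaf(switch(nm, true = "true", false = "false", pi = "pi",
                       infinity = "INF", notanumber = "NaN")))
  }
  if (nm == "exponentiale") return(leaf("exponentiale"))
  if (nm == "apply") {
    kids <- xml2::xml_children(node)
    op <- xml2::xml_name(kids[[1]])
    args <- purrr::map(kids[-1], serialize_math_node)
    wrap <- function(a) if (isTRUE(a$infix)) paste0("(", a$txt, ")") else a$txt
    if (op == "minus") {
      if (length(args) == 1L) {
        return(list(txt = paste0("-", wrap(args[[1]])), infix = FALSE))
      }
      return(list(txt = paste(wrap(args[[1]]), "-", wrap(args[[2]])),
                  infix = TRUE))
    }
    if (op %in% names(MATHML_INFIX)) {
      txt <- paste(purrr::map_chr(args, wrap),
                   collapse = paste0(" ", MATHML_INFIX[[op]], " "))
      return(list(txt = txt, infix = TRUE))
    }
    if (op == "not") {
      return(leaf(paste0("!(", args[[1]]$txt, ")")))
    }
    if (op == "root") {
      return(leaf(paste0("sqrt(", args[[length(args)]]$txt, ")")))
    }
    fname <- if (op == "ci") trimws(xml2::xml_text(kids[[1]])) else op
    return(leaf(paste0(fname, "(",
                       paste(purrr::map_chr(args, "txt"), collapse = ", "),
                       ")")))
  }
  if (nm == "lambda") {
    kids <- xml2::xml_children(node)
    bvars <- purrr::map_chr(
      purrr::keep(kids, function(k) xml2::xml_name(k) == "bvar"),
      function(k) trimws(xml2::xml_text(k)))
    body <- serialize_math_node(kids[[length(kids)]])
    return(leaf(paste0("lambda(", paste(c(bvars, body$txt), collapse = ", "),
                       ")")))
  }
  if (nm == "piecewise") {
    kids <- xml2::xml_children(node)
    inner <- purrr::map_chr(kids, function(k) {
      parts <- purrr::map_chr(xml2::xml_children(k), function(kk)
        serialize_math_node(kk)$txt)
      paste(parts, collapse = ", ")
    })
    return(leaf(paste0("piecewise(", paste(inner, collapse = ", "), ")")))
  }
  leaf(trimws(xml2::xml_text(node)))
}
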