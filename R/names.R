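#' Canonicalize a schema or SBML name for matching
#'
#' Schema labels, properties and relationship types are matched against SBML
#' component kinds and attribute names case- and punctuation-insensitively:
#' all non-alphanumeric characters are stripped and the result is lower-cased.
#' `"UnitDefinition"`, `"unitDefinition"` and `"unit_definition"` all map to
#' `"unitdefinition"`. The function is idempotent.
#'
#' @param name Non-empty character vector of names.
#' @return Character vector of canonical forms.
#' @examples
#' normalize_name(c("UnitDefinition", "HAS_LOWERFLUXBOUND"))
#' @export
normalize_name <- function(name) {
  if (length(name) == 0L) return(character())
  if (any(is.na(name)) || any(!nzchar(name))) {
    abort("`name` must be non-empty.", class = "sbmlgraph_name_error")
  }
  out <- tolower(gsub("[^A-Za-z0-9]+", "", name))
  if (any(!nzchar(out))) {
    abort("`name` contains no alphanumeric characters.",
          class = "sbmlgraph_name_error")
  }
  out
}

# Relationship types conventionally start with a verb token (HAS_UNITS,
# IN_COMPARTMENT, IS_REACTANT). For matching a type against an SBML attribute
# or listOf* container the leading {HAS, IS, IN} tokens are dropped before
# canonicalization, so HAS_UNITS matches the `units` attribute and
# IN_COMPARTMENT the `compartment` attribute. Tokens are split on punctuation
# and on lower-to-upper case boundaries (hasUnits works too). If every token
# is a verb, the full canonical form is returned unchanged.
normalize_relationship <- function(type) {
  stopifnot(length(type) == 1L)
  spaced <- gsub("([a-z0-9])([A-Z])", "\\1 \\2", type)
  tokens <- strsplit(spaced, "[^A-Za-z0-9]+")[[1]]
  tokens <- tokens[nzchar(tokens)]
  verbs <- c("has", "is", "in")
  while (length(tokens) > 1L && tolower(tokens[[1]]) %in% verbs) {
    tokens <- tokens[-1L]
  }
  if (length(tokens) == 0L) return(normalize_name(type))
  normalize_name(paste(tokens, collapse = ""))
}

# Singular/plural-insensitive comparison: a trailing "s" on either side is
# ignored (listOfProducts <-> HAS_PRODUCT).
names_match_sp <- function(a, b) {
  strip_s <- function(x) sub("s$", "", x)
  a == b | strip_s(a) == strip_s(b)
}

is_listof <- function(kind) startsWith(normalize_name(kind), "listof")

# canonical name of a listOf container's content: listOfProducts -> products
listof_content <- function(kind) sub("^listof", "", normalize_name(kind))
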