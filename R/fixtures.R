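# Deterministic synthetic-SBML generation and an independent XML scan
# oracle. The generator is a pure function of its spec (own linear
# congruential stream, no global RNG); the oracle shares no code with the
# mapper — it answers the same questions by direct XPath-style scanning, so
# agreement between the two is meaningful evidence.

#' Describe a synthetic SBML model
#'
#' The generated models emulate the shape of reaction-based models:
#' compartments, species assigned round-robin, reactions drawing reactant
#' and product species from a seeded pseudo-random stream, and optionally
#' the fbc (flux bounds + gene products), groups, layout and qual package
#' layers. The defaults give the two-species/one-reaction micro-model used
#' throughout the documentation.
#'
#' @param n_compartments,n_species,n_reactions Component counts (>= 0).
#' @param n_reactants,n_products Participants per reaction.
#' @param packages Subset of `c("fbc", "groups", "layout", "qual")`.
#' @param include_idless Also emit an event with an id-less eventAssignment
#'   (exercises surrogate keys).
#' @param seed Integer seed of the generator's private stream.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_compartments = 1L, n_species = 2L,
                         n_reactions = 1L, n_reactants = 1L,
                         n_products = 1L, packages = character(),
                         include_idless = FALSE, seed = 1L) {
  stopifnot(n_compartments >= 0, n_species >= 0, n_reactions >= 0,
            n_reactants >= 0, n_products >= 0,
            all(packages %in% c("fbc", "groups", "layout", "qual")))
  structure(list(n_compartments = as.integer(n_compartments),
                 n_species = as.integer(n_species),
                 n_reactions = as.integer(n_reactions),
                 n_reactants = as.integer(n_reactants),
                 n_products = as.integer(n_products),
                 packages = packages,
                 include_idless = isTRUE(include_idless),
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

# private LCG stream (Lehmer-style), independent of R's global RNG
lcg_stream <- function(seed) {
  state <- (as.numeric(seed) %% 2147483647) + 1
  function(n_max) {
    state <<- (state * 48271) %% 2147483647
    as.integer(state %% n_max) + 1L
  }
}

#' Generate a synthetic SBML document
#'
#' Produces well-formed SBML Level 3 Version 2 text realizing a
#' [fixture_spec()]: byte-identical output for identical specs. With `fbc`,
#' reactions get lower/upper flux-bound parameters and one gene product
#' each, linked through `geneProductAssociation`/`geneProductRef`; `groups`
#' adds a group whose members reference the species; `layout` adds a layout
#' with dimensions and a species glyph; `qual` adds qualitative species and
#' a transition with an input.
#'
#' @param spec A `fixture_spec`.
#' @return SBML document text (single string).
#' @examples
#' cat(substr(generate_model(fixture_spec()), 1, 200))
#' @export
generate_model <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  draw <- lcg_stream(spec$seed)
  use <- function(pkg) pkg %in% spec$packages
  ns <- c('xmlns="http://www.sbml.org/sbml/level3/version2/core"')
  if (use("fbc")) {
    ns <- c(ns,
      'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"',
      'fbc:required="false"')
  }
  if (use("groups")) {
    ns <- c(ns,
      'xmlns:groups="http://www.sbml.org/sbml/level3/version1/groups/version1"',
      'groups:required="false"')
  }
  if (use("layout")) {
    ns <- c(ns,
      'xmlns:layout="http://www.sbml.org/sbml/level3/version1/layout/version1"',
      'layout:required="false"')
  }
  if (use("qual")) {
    ns <- c(ns,
      'xmlns:qual="http://www.sbml.org/sbml/level3/version1/qual/version1"',
      'qual:required="false"')
  }
  L <- character()
  push <- function(...) L[[length(L) + 1L]] <<- paste0(...)
  push('<?xml version="1.0" encoding="UTF-8"?>')
  push('<sbml ', paste(ns, collapse = " "), ' level="3" version="2">')
  model_attrs <- '  <model id="synthmodel" name="synthetic model"'
  if (use("fbc")) model_attrs <- paste0(model_attrs, ' fbc:strict="false"')
  push(model_attrs, ">")

  comp_ids <- sprintf("C%d", seq_len(spec$n_compartments))
  if (spec$n_compartments > 0L) {
    push("    <listOfCompartments>")
    for (cid in comp_ids) {
      push('      <compartment id="', cid, '" name="compartment ', cid,
           '" size="1" constant="true"/>')
    }
    push("    </listOfCompartments>")
  }

  sp_ids <- sprintf("S%d", seq_len(spec$n_species))
  sp_comp <- if (spec$n_compartments > 0L) {
    comp_ids[((seq_len(spec$n_species) - 1L) %% spec$n_compartments) + 1L]
  } else rep(NA_character_, spec$n_species)
  if (spec$n_species > 0L) {
    push("    <listOfSpecies>")
    for (i in seq_len(spec$n_species)) {
      comp <- if (is.na(sp_comp[[i]])) "" else
        paste0(' compartment="', sp_comp[[i]], '"')
      push('      <species id="', sp_ids[[i]], '" name="species ',
           sp_ids[[i]], '"', comp,
           ' hasOnlySubstanceUnits="false" boundaryCondition="false"',
           ' constant="false"/>')
    }
    push("    </listOfSpecies>")
  }

  if (use("fbc") && spec$n_reactions > 0L) {
    push("    <listOfParameters>")
    push('      <parameter id="lb" value="-1000" constant="true"/>')
    push('      <parameter id="ub" value="1000" constant="true"/>')
    push("    </listOfParameters>")
  }

  gene_ids <- sprintf("G%d", seq_len(spec$n_reactions))
  rx_participants <- list()
  if (spec$n_reactions > 0L) {
    push("    <listOfReactions>")
    for (r in seq_len(spec$n_reactions)) {
      rid <- sprintf("R%d", r)
      fbc_attrs <- if (use("fbc")) {
        ' fbc:lowerFluxBound="lb" fbc:upperFluxBound="ub"'
      } else ""
      push('      <reaction id="', rid, '" name="reaction ', rid,
           '" reversible="false"', fbc_attrs, ">")
      # products avoid the reaction's own reactants when other species
      # exist: a species converting into itself is not a meaningful reaction
      pick <- function(k, pool) {
        if (length(pool) == 0L || k == 0L) return(character())
        unique(vapply(seq_len(k), function(.)
          pool[[draw(length(pool))]], character(1)))
      }
      reactants <- pick(spec$n_reactants, sp_ids)
      prod_pool <- setdiff(sp_ids, reactants)
      if (length(prod_pool) == 0L) prod_pool <- sp_ids
      products <- pick(spec$n_products, prod_pool)
      rx_participants[[rid]] <- list(reactants = reactants,
                                     products = products)
      if (length(reactants) > 0L) {
        push("        <listOfReactants>")
        for (s in reactants) {
          push('          <speciesReference species="', s,
               '" stoichiometry="1" constant="true"/>')
        }
        push("        </listOfReactants>")
      }
      if (length(products) > 0L) {
        push("        <listOfProducts>")
        for (s in products) {
          push('          <speciesReference species="', s,
               '" stoichiometry="1" constant="true"/>')
        }
        push("        </listOfProducts>")
      }
      if (use("fbc")) {
        push("        <fbc:geneProductAssociation>")
        push('          <fbc:geneProductRef fbc:geneProduct="',
             gene_ids[[r]], '"/>')
        push("        </fbc:geneProductAssociation>")
      }
      push("      </reaction>")
    }
    push("    </listOfReactions>")
  }

  if (spec$include_idless) {
    push("    <listOfEvents>")
    push('      <event useValuesFromTriggerTime="true">')
    push("        <listOfEventAssignments>")
    push('          <eventAssignment variable="',
         if (spec$n_species > 0L) sp_ids[[1]] else "x", '"/>')
    push("        </listOfEventAssignments>")
    push("      </event>")
    push("    </listOfEvents>")
  }

  if (use("fbc") && spec$n_reactions > 0L) {
    push("    <fbc:listOfGeneProducts>")
    for (r in seq_len(spec$n_reactions)) {
      push('      <fbc:geneProduct fbc:id="', gene_ids[[r]],
           '" fbc:label="gene ', gene_ids[[r]], '"/>')
    }
    push("    </fbc:listOfGeneProducts>")
  }

  if (use("groups") && spec$n_species > 0L) {
    push("    <groups:listOfGroups>")
    push('      <groups:group groups:id="grp1" groups:kind="collection">')
    push("        <groups:listOfMembers>")
    for (s in sp_ids) {
      push('          <groups:member groups:idRef="', s, '"/>')
    }
    push("        </groups:listOfMembers>")
    push("      </groups:group>")
    push("    </groups:listOfGroups>")
  }

  if (use("layout")) {
    push("    <layout:listOfLayouts>")
    push('      <layout:layout layout:id="lay1">')
    push('        <layout:dimensions layout:width="400" layout:height="300"/>')
    if (spec$n_species > 0L) {
      push('        <layout:listOfSpeciesGlyphs>')
      push('          <layout:speciesGlyph layout:id="glyph_S1"',
           ' layout:species="', sp_ids[[1]], '"/>')
      push('        </layout:listOfSpeciesGlyphs>')
    }
    push("      </layout:layout>")
    push("    </layout:listOfLayouts>")
  }

  if (use("qual") && spec$n_species > 0L) {
    push("    <qual:listOfQualitativeSpecies>")
    for (s in utils::head(sp_ids, 2L)) {
      push('      <qual:qualitativeSpecies qual:id="q_', s,
           '" qual:compartment="', if (is.na(sp_comp[[1]])) "C1" else
             sp_comp[[match(s, sp_ids)]],
           '" qual:constant="false"/>')
    }
    push('    </qual:listOfQualitativeSpecies>')
    push('    <qual:listOfTransitions>')
    push('      <qual:transition qual:id="tr1">')
    push('        <qual:listOfInputs>')
    push('          <qual:input qual:id="in1" qual:qualitativeSpecies="q_',
         sp_ids[[1]], '" qual:transitionEffect="none"/>')
    push('        </qual:listOfInputs>')
    push('      </qual:transition>')
    push('    </qual:listOfTransitions>')
  }

  push("  </model>")
  push("</sbml>")
  paste(L, collapse = "\n")
}

# --- reference-scan oracle ------------------------------------------------

#' Independent ground truth for a (document, schema) pair
#'
#' A deliberately naive second implementation used to check the mapper:
#' node counts come from counting elements by tag name; relationship counts
#' from a direct reference scan over the raw XML that mirrors the three
#' resolution strategies (attribute named after the target, attribute or
#' listOf* child named after the relationship, containment/descendant
#' reference closure), with the same first-non-empty precedence. It shares
#' no code with [map_document()].
#'
#' @param xml_text SBML text or path.
#' @param schema An `sbml_schema` or Arrows export text/path.
#' @return A tibble in the [graph_stats()] layout (`element`, `name`, `n`).
#' @export
ground_truth <- function(xml_text, schema) {
  if (!inherits(schema, "sbml_schema")) schema <- load_schema(schema)
  xml <- xml2::read_xml(read_text_arg(xml_text))
  model <- xml2::xml_find_first(xml, "./*[local-name()='model']")
  all_elems <- c(list(model),
                 as.list(xml2::xml_find_all(model, ".//*")))
  elem_names <- vapply(all_elems, xml2::xml_name, character(1))
  keep <- !(elem_names %in% c("math", "annotation", "notes")) &
    !oracle_under(all_elems, c("math", "annotation", "notes"))
  all_elems <- all_elems[keep]
  elem_names <- elem_names[keep]
  elem_norm <- normalize_name(elem_names)

  oracle_attrs <- function(el) {
    a <- xml2::xml_attrs(el)
    names(a) <- sub("^.*:", "", names(a))
    a[!(names(a) %in% c("xmlns", "schemaLocation"))]
  }
  ids_of <- function(label) {
    hits <- all_elems[elem_norm == normalize_name(label)]
    ids <- vapply(hits, function(e) {
      a <- oracle_attrs(e)
      if ("id" %in% names(a)) a[["id"]] else NA_character_
    }, character(1))
    ids[!is.na(ids)]
  }

  rows <- list()
  for (i in seq_len(nrow(schema$nodes))) {
    lab <- schema$nodes$labels[[i]][[1]]
    rows[[length(rows) + 1L]] <- tibble::tibble(
      element = "node", name = lab,
      n = sum(elem_norm == normalize_name(lab)))
  }

  for (i in seq_len(nrow(schema$relationships))) {
    rl <- as.list(schema$relationships[i, ])
    src_lab <- schema$nodes$labels[[
      match(rl$source_key, schema$nodes$key)]][[1]]
    tgt_lab <- schema$nodes$labels[[
      match(rl$target_key, schema$nodes$key)]][[1]]
    tgt_ids <- ids_of(tgt_lab)
    tgt_norm <- normalize_name(tgt_lab)
    rel_norm <- normalize_relationship(rl$type)
    src_elems <- all_elems[elem_norm == normalize_name(src_lab)]
    n_pairs <- 0L
    for (s in src_elems) {
      a <- oracle_attrs(s)
      an <- if (length(a)) normalize_name(names(a)) else character()
      # strategy 1: attribute named after the target
      hit <- a[an == tgt_norm]
      found <- unique(hit[hit %in% tgt_ids])
      # strategy 2: attribute or direct listOf* child named after the type
      if (length(found) == 0L) {
        hit <- a[names_match_sp(an, rel_norm)]
        found <- unique(hit[hit %in% tgt_ids])
      }
      if (length(found) == 0L) {
        vals <- character()
        for (ch in xml2::xml_children(s)) {
          chn <- normalize_name(xml2::xml_name(ch))
          if (!startsWith(chn, "listof")) next
          if (!names_match_sp(sub("^listof", "", chn), rel_norm)) next
          for (m in xml2::xml_children(ch)) {
            ma <- oracle_attrs(m)
            man <- if (length(ma)) normalize_name(names(ma)) else character()
            vals <- c(vals, unname(ma[man == tgt_norm]))
          }
        }
        found <- unique(vals[vals %in% tgt_ids])
      }
      # strategy 3: containment (direct descendants, then referenced ids)
      if (length(found) == 0L) {
        desc <- xml2::xml_find_all(s, ".//*")
        dn <- normalize_name(vapply(desc, xml2::xml_name, character(1)))
        direct <- desc[dn == tgt_norm]
        if (length(direct) > 0L) {
          found <- unique(vapply(seq_along(direct), function(j) {
            da <- oracle_attrs(direct[[j]])
            if ("id" %in% names(da)) da[["id"]] else
              paste0("surrogate", j)
          }, character(1)))
        } else if (length(tgt_ids) > 0L) {
          vals <- unlist(lapply(desc, function(d) unname(oracle_attrs(d))))
          found <- unique(vals[vals %in% tgt_ids])
        }
      }
      n_pairs <- n_pairs + length(found)
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      element = "relationship", name = rl$type, n = n_pairs)
  }
  dplyr::bind_rows(rows) |>
    dplyr::group_by(.data$element, .data$name) |>
    dplyr::summarise(n = sum(.data$n), .groups = "drop") |>
    dplyr::arrange(.data$element, .data$name)
}

oracle_under <- function(elems, ancestors) {
  vapply(elems, function(e) {
    p <- xml2::xml_parent(e)
    while (!inherits(p, "xml_missing") &&
           xml2::xml_name(p) != "model" && xml2::xml_name(p) != "sbml") {
      if (xml2::xml_name(p) %in% ancestors) return(TRUE)
      pp <- xml2::xml_parent(p)
      if (inherits(pp, "xml_missing")) break
      p <- pp
    }
    FALSE
  }, logical(1))
}
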