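test_that("a species neighborhood at radius 1 covers its reactions and
           compartment", {
  g <- map_document(toy1_xml(), metabolic_schema(), tag = "t")
  hood <- species_neighborhood(g, "species S1", radius = 1L)
  labs <- sort(hood$nodes$label)
  expect_equal(labs, c("Compartment", "Reaction", "Species"))
  expect_true("S1" %in% hood$nodes$id)
  # radius larger than the diameter returns the whole connected component
  all_of_it <- species_neighborhood(g, "species S1", radius = 10L)
  expect_equal(nrow(all_of_it$nodes), nrow(g$nodes))
  # unknown species: empty graph, not an error
  none <- species_neighborhood(g, "unobtainium", radius = 1L)
  expect_equal(nrow(none$nodes), 0L)
})

test_that("neighborhoods grow monotonically with the radius", {
  g <- chain_graph(6L)
  sizes <- purrr::map_int(1:5, function(r)
    nrow(species_neighborhood(g, "S3", radius = r)$nodes))
  expect_true(all(diff(sizes) >= 0))
})

test_that("dense-node flagging is exact at the threshold", {
  g <- chain_graph(4L)
  flagged <- function(gg) {
    gg$nodes$id[purrr::map_lgl(gg$nodes$properties, function(p)
      isTRUE(p$dense))]
  }
  all_flagged <- flag_dense_nodes(g, "Species", 0L)
  expect_setequal(flagged(all_flagged), c("S1", "S2", "S3", "S4"))
  max_deg <- max(purrr::map_int(g$nodes$key, node_degree, graph = g))
  none_flagged <- flag_dense_nodes(g, "Species", max_deg + 1L)
  expect_equal(length(flagged(none_flagged)), 0L)
  # only the hub exceeds a threshold of 2 in a star model
  hub <- map_document(hub_model_xml(4), metabolic_schema(), tag = "t")
  hub_flagged <- flag_dense_nodes(hub, "Species", 3L)
  expect_equal(flagged(hub_flagged), "hub")
})

test_that("producer search on a linear chain finds the single path", {
  g <- chain_graph(3L)  # S1 -> R1 -> S2 -> R2 -> S3
  paths <- producers_at_distance(g, "S3", "c", n_reactions = 2L)
  expect_equal(nrow(paths), 1L)
  expect_equal(paths$source_id, "S1")
  expect_equal(paths$target_id, "S3")
  steps <- paths$path[[1]]
  expect_equal(length(steps), 9L)  # 5 node keys interleaved with 4 types
  expect_equal(steps[c(2, 4, 6, 8)],
               rep(c("IS_REACTANT", "HAS_PRODUCT"), 2))
  # distances longer than any path yield nothing
  expect_equal(nrow(producers_at_distance(g, "S3", "c", 5L)), 0L)
  # unknown compartment yields nothing
  expect_equal(nrow(producers_at_distance(g, "S3", "x", 2L)), 0L)
})

test_that("producer paths never revisit a node", {
  # S1 -> R1 -> S2 -> R2 -> S1 cycle: no 2-reaction path may end where it
  # started
  g <- chain_graph(2L)
  g <- upsert_node(g, list(label = "Reaction", id = "Rback", tag = "chain"))
  rb <- find_nodes(g, "Reaction", "Rback")
  g <- upsert_relationship(g, list(type = "IS_REACTANT", source = rb,
                                   target = find_nodes(g, "Species", "S2")))
  g <- upsert_relationship(g, list(type = "HAS_PRODUCT", source = rb,
                                   target = find_nodes(g, "Species", "S1")))
  paths <- producers_at_distance(g, "S1", "c", n_reactions = 2L)
  expect_equal(nrow(paths), 0L)
})

test_that("producer search matches exhaustive DFS enumeration", {
  for (seed in c(11L, 23L, 37L, 58L)) {
    g <- random_metabolic_graph(n_species = 12L, n_reactions = 14L,
                                seed = seed)
    for (n_rx in 1:3) {
      got <- producers_at_distance(g, "S1", "e", n_reactions = n_rx)
      want <- dfs_producer_paths(g, "S1", "e", n_rx)
      canon <- function(paths) sort(purrr::map_chr(paths, paste,
                                                   collapse = ">"))
      got_keys <- if (nrow(got) == 0L) character() else
        canon(purrr::map(got$path, function(p)
          p[seq(1, length(p), by = 2)]))
      want_keys <- if (length(want) == 0L) character() else canon(want)
      expect_equal(got_keys, want_keys,
                   info = paste("seed", seed, "n_rx", n_rx))
    }
  }
})

test_that("species-reference contraction rewires edges onto species", {
  tag <- "t"
  g <- property_graph()
  g <- upsert_node(g, list(label = "Reaction", id = "R1", tag = tag))
  g <- upsert_node(g, list(label = "Species", id = "S2", tag = tag))
  g <- upsert_node(g, list(label = "SpeciesReference", id = "sr1", tag = tag,
                           properties = list(species = "S2")))
  rk <- find_nodes(g, "Reaction")
  sk <- find_nodes(g, "Species")
  srk <- find_nodes(g, "SpeciesReference")
  g <- upsert_relationship(g, list(type = "HAS_PRODUCT", source = rk,
                                   target = srk))
  g <- upsert_relationship(g, list(type = "REFERS_TO", source = srk,
                                   target = sk))
  out <- contract_species_references(g)
  expect_equal(nrow(out$nodes), 2L)
  rels <- tidy(out, "relationships")
  expect_true(any(rels$type == "HAS_PRODUCT" & rels$source_id == "R1" &
                  rels$target_id == "S2"))
  # the reference's own edge collapses to a dropped self-loop
  expect_false(any(rels$type == "REFERS_TO"))
  # Species/Reaction counts conserved, edges never increase
  expect_equal(sum(out$nodes$label == "Species"),
               sum(g$nodes$label == "Species"))
  expect_equal(sum(out$nodes$label == "Reaction"),
               sum(g$nodes$label == "Reaction"))
  expect_lte(nrow(out$relationships), nrow(g$relationships))
})

test_that("contraction without species references is the identity", {
  g <- map_document(toy1_xml(), metabolic_schema(), tag = "t")
  out <- contract_species_references(g)
  expect_equal(out$nodes, g$nodes)
  expect_equal(out$relationships, g$relationships)
})

test_that("unresolvable species references are dropped with a warning", {
  g <- property_graph()
  g <- upsert_node(g, list(label = "SpeciesReference", id = "sr1", tag = "t",
                           properties = list(species = "ghost")))
  expect_warning(out <- contract_species_references(g),
                 class = "sbmlgraph_unresolved_reference")
  expect_equal(nrow(out$nodes), 0L)
})

test_that("degree pruning removes exactly the under-connected species", {
  hub <- map_document(hub_model_xml(4), metabolic_schema(), tag = "t")
  # hub touches 4 reactions, peripherals touch 1
  expect_equal(nrow(hub$nodes[hub$nodes$label == "Species", ]), 5L)
  pruned <- prune_species_by_degree(hub, min_reactions = 4L)
  kept <- pruned$nodes$id[pruned$nodes$label == "Species"]
  expect_equal(kept, "hub")
  # edges to removed species are gone; graph still validates
  expect_true(all(c(pruned$relationships$source,
                    pruned$relationships$target) %in% pruned$nodes$key))
  # min_reactions 0 is the identity
  same <- prune_species_by_degree(hub, 0L)
  expect_equal(nrow(same$nodes), nrow(hub$nodes))
  # single pass: pruning is not cascaded to newly under-connected species
  chain <- chain_graph(3L)
  once <- prune_species_by_degree(chain, 2L)
  expect_equal(sort(once$nodes$id[once$nodes$label == "Species"]), "S2")
})

test_that("synthetic model pair differs by one reaction in the hub
           neighborhood", {
  ga <- map_document(hub_model_xml(3, "modelA"), metabolic_schema(),
                     tag = "modelA")
  gb <- map_document(hub_model_xml(4, "modelB"), metabolic_schema(),
                     tag = "modelB")
  merged <- merge_graphs(ga, gb)
  hood <- species_neighborhood(merged, "fumarate", radius = 1L)
  by_tag <- split(hood$nodes$label, hood$nodes$tag)
  expect_equal(sum(by_tag$modelB == "Reaction") -
                 sum(by_tag$modelA == "Reaction"), 1L)
})
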