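test_that("the proximity transform has its stated fixed points", {
  expect_equal(proximity(0), 1)
  expect_equal(proximity(Inf), 0)
  expect_equal(proximity(1), 0.5)
  expect_equal(proximity(c(0, 1, 3, Inf)), c(1, 0.5, 0.25, 0))
  expect_error(proximity(-1), "non-negative")
})

test_that("the distance back-transform inverts the mean proximity", {
  expect_equal(mean_arc_distance(c(1, 1, 1)), 0)
  expect_equal(mean_arc_distance(c(1, 0.5)), 1 / 0.75 - 1)
  expect_identical(mean_arc_distance(c(0, 0)), Inf)
  expect_error(mean_arc_distance(numeric(0)))
})

test_that("set proximities follow the worked path example", {
  g <- igraph::make_graph(~ a - b - c)
  # gene b, targets {a, c}: both at distance 1 -> shortest 0.5, average 0.5
  res <- set_proximities(g, "b", c("a", "c"))
  expect_equal(res$shortest, 0.5)
  expect_equal(res$average, 0.5)
  # a gene in the target set has shortest proximity 1 (self-distance 0)
  res_a <- set_proximities(g, "a", c("a", "c"))
  expect_equal(res_a$shortest, 1)
  expect_true(res_a$in_target)
})

test_that("genes in components without targets score zero", {
  g <- igraph::make_graph(~ a - b, c - d)
  res <- set_proximities(g, "c", c("a", "b"))
  expect_equal(res$shortest, 0)
  expect_equal(res$average, 0)
})

test_that("an empty effective target set yields missing proximities", {
  g <- igraph::make_graph(~ a - b)
  expect_warning(res <- set_proximities(g, "a", "zz"), "no target")
  expect_true(is.na(res$shortest) && is.na(res$average))
  expect_error(set_proximities(g, "zz", "a"), "absent")
})

test_that("shortest proximity dominates average proximity", {
  set.seed(31)
  for (i in 1:10) {
    g <- random_layer(40, 0.08)
    nodes <- igraph::V(g)$name
    targets <- sample(nodes, 6)
    res <- set_proximities(g, nodes, targets)
    expect_true(all(res$shortest >= res$average - 1e-12))
  }
})

test_that("proximities match an independent BFS oracle", {
  set.seed(17)
  for (i in 1:8) {
    g <- random_layer(35, 0.09)
    nodes <- igraph::V(g)$name
    targets <- sample(nodes, 5)
    queries <- sample(nodes, 4)
    em <- graph_edge_matrix(g)
    res <- set_proximities(g, queries, targets)
    for (j in seq_along(queries)) {
      d <- bfs_distances(em, nodes, queries[j])[targets]
      p <- ifelse(is.infinite(d), 0, 1 / (d + 1))
      expect_equal(res$shortest[j], max(p), tolerance = 1e-12)
      expect_equal(res$average[j], mean(p), tolerance = 1e-12)
    }
  }
})

test_that("indirect cluster interactions count neighbours' clusters only", {
  arc_map <- data.frame(ard_id = c("stroke", "diabetes", "gout"),
                        arc_id = c("Cardiovascular", "Endocrine", "Musculoskeletal"))
  g <- igraph::make_graph(~ X - Y, X - Z)
  # Y carries stroke (Cardiovascular), Z carries diabetes (Endocrine)
  assoc <- associations_from_pairs(
    data.frame(gene = c("Y", "Z"), ard_id = c("stroke", "diabetes")), arc_map)
  expect_equal(count_arc_interactions(g, assoc, "X")[["X"]], 2)
  expect_equal(count_arc_interactions(g, assoc, "X", level = "ard")[["X"]], 2)

  # a gene whose neighbours carry no association scores zero even if the gene
  # itself is disease-associated (direct associations do not count)
  assoc2 <- associations_from_pairs(
    data.frame(gene = "X", ard_id = "stroke"), arc_map)
  expect_equal(count_arc_interactions(g, assoc2, "X")[["X"]], 0)

  # three neighbours all in one cluster -> 1
  g4 <- igraph::make_graph(~ X - A, X - B, X - C)
  assoc3 <- associations_from_pairs(
    data.frame(gene = c("A", "B", "C"), ard_id = "stroke"), arc_map)
  expect_equal(count_arc_interactions(g4, assoc3, "X")[["X"]], 1)
  expect_error(count_arc_interactions(g4, assoc3, "nope"), "absent")
})

test_that("per-cluster neighbour counts enumerate adjacency", {
  arc_map <- data.frame(ard_id = c("d1", "d2"), arc_id = c("c1", "c2"))
  g <- igraph::make_star(4, mode = "undirected", center = 1)
  igraph::V(g)$name <- c("hub", "l1", "l2", "l3")
  assoc <- associations_from_pairs(
    data.frame(gene = c("l1", "l2", "l3"), ard_id = "d1"), arc_map)
  counts <- count_disease_neighbours(g, assoc, "hub")
  expect_equal(unname(counts["hub", "c1"]), 3L)
  # isolated-in-set gene: all counts zero
  counts_leaf <- count_disease_neighbours(g, assoc, "l1")
  expect_true(all(counts_leaf == 0)) # only neighbour is the unassociated hub
})

test_that("summed neighbour counts bound the distinct-cluster interaction count", {
  study <- small_study()
  assoc <- study_assoc(study)
  layer <- study$layers$PPI
  counts <- count_arc_interactions(layer, assoc)
  per_arc <- count_disease_neighbours(layer, assoc)
  expect_true(all(rowSums(per_arc) >= counts[rownames(per_arc)]))
  expect_true(all(counts <= study$config$n_arcs))
})

test_that("per-cluster proximity matrices respect membership and bounds", {
  study <- small_study()
  assoc <- study_assoc(study)
  layer <- study$layers$PPI
  ps <- trait_proximity_matrix(layer, assoc, "arc", "shortest")
  pa <- trait_proximity_matrix(layer, assoc, "arc", "average")
  expect_equal(dim(ps), c(igraph::vcount(layer), study$config$n_arcs))
  expect_true(all(ps >= pa - 1e-12))
  expect_true(all(ps >= 0 & ps <= 1))
  # a disease-associated gene present in the layer has proximity 1 to its ARC
  sets <- split(assoc$arc$gene, assoc$arc$arc_id)
  arc1 <- names(sets)[1]
  member <- intersect(sets[[arc1]], rownames(ps))[1]
  expect_equal(ps[member, arc1], 1)
})
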