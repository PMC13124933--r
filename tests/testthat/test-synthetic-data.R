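test_that("identical config and seed give a bit-identical study", {
  cfg <- small_study_config(seed = 42)
  s1 <- generate_study(cfg)
  s2 <- generate_study(cfg)
  expect_identical(study_fingerprint(s1), study_fingerprint(s2))
})

test_that("planted pleiotropic-like genes span at least four disease clusters", {
  study <- small_study()
  arc_of <- setNames(study$arc_map$arc_id, study$arc_map$ard_id)
  # brute-force count of distinct ARCs from the SNP table itself
  snp_genes <- map_snps_to_genes(study$snp_table, study$gene_ranges,
                                 arc_map = study$arc_map)
  arcs_per_gene <- tapply(snp_genes$arc$arc_id, snp_genes$arc$gene,
                          function(a) length(unique(a)))
  expect_true(all(study$pleio_like %in% names(arcs_per_gene)))
  expect_true(all(arcs_per_gene[study$pleio_like] >= 4))
})

test_that("pleiotropy_rate = 0 gives exactly one ARD per non-planted associated gene", {
  study <- generate_study(small_study_config(seed = 3, pleiotropy_rate = 0))
  tr <- study$truth[!(study$truth$gene %in% study$pleio_like), ]
  expect_true(all(table(tr$gene) == 1))
})

test_that("planted set sizes exceeding the universe are a configuration error", {
  expect_error(study_config(n_genes = 30, planted_ageing_size = 20,
                            planted_pleio_size = 20),
               "planted set sizes")
  expect_error(study_config(n_arcs = 10, n_ards = 5), "n_arcs")
  expect_error(study_config(pleiotropy_rate = 1.5), "probability")
  expect_error(study_config(n_genes = 0), "positive")
})

test_that("generated pathway graphs are simple DAGs with roots and leaves", {
  cfg <- small_study_config(seed = 5)
  for (seed in 1:5) {
    set.seed(seed)
    dag <- generate_kegg_dag(cfg, genes = paste0("n", 1:40), depth = 4)
    expect_true(igraph::is_dag(dag))
    expect_false(igraph::any_loop(dag))
    expect_false(igraph::any_multiple(dag))
    indeg <- igraph::degree(dag, mode = "in")
    outdeg <- igraph::degree(dag, mode = "out")
    expect_gte(sum(indeg == 0), 1)
    expect_gte(sum(outdeg == 0), 1)
  }
})

test_that("layered DAG paths never exceed the configured depth", {
  cfg <- small_study_config(seed = 7)
  set.seed(7)
  depth <- 4
  dag <- generate_kegg_dag(cfg, genes = paste0("n", 1:25), depth = depth)
  roots <- igraph::V(dag)$name[igraph::degree(dag, mode = "in") == 0]
  # exhaustive path enumeration on the small instance
  longest <- 0
  for (r in roots) {
    paths <- igraph::all_simple_paths(dag, from = r, mode = "out")
    if (length(paths) > 0) {
      longest <- max(longest, max(vapply(paths, length, 1L)) - 1L)
    }
  }
  expect_lte(longest, depth - 1)
})

test_that("a single-gene pathway graph is both root and leaf", {
  dag <- generate_kegg_dag(small_study_config(), genes = "only")
  expect_equal(igraph::vcount(dag), 1)
  expect_equal(igraph::degree(dag, mode = "in")[["only"]], 0)
  expect_equal(igraph::degree(dag, mode = "out")[["only"]], 0)
})

test_that("coexpression generator yields a symmetric unit-diagonal matrix in [0,1]", {
  cfg <- study_config(n_genes = 60, planted_ageing_size = 5, planted_pleio_size = 5)
  genes <- rownames(generate_coexpression_matrix(cfg))
  mods <- list(genes[1:10], genes[11:20])
  M <- generate_coexpression_matrix(cfg, mods, within = 0.6, between = 0.1)
  expect_identical(M, t(M))
  expect_true(all(diag(M) == 1))
  expect_true(all(M >= 0 & M <= 1))
  # planted blocks exceed the background in the configured direction
  block_mean <- function(set) {
    sub <- M[set, set]
    mean(sub[lower.tri(sub)])
  }
  bg <- M[genes[21:40], genes[41:60]]
  expect_gt(block_mean(mods[[1]]), mean(bg) + 0.3)
  expect_gt(block_mean(mods[[2]]), mean(bg) + 0.3)
})

test_that("zero within/between margin yields indistinguishable block means", {
  cfg <- study_config(n_genes = 80, planted_ageing_size = 5, planted_pleio_size = 5)
  genes <- rownames(generate_coexpression_matrix(cfg))
  mods <- list(genes[1:25])
  M <- generate_coexpression_matrix(cfg, mods, within = 0.3, between = 0.3)
  sub <- M[mods[[1]], mods[[1]]]
  bg <- M[genes[26:80], genes[26:80]]
  expect_lt(abs(mean(sub[lower.tri(sub)]) - mean(bg[lower.tri(bg)])), 0.05)
})

test_that("a study round-trips through its on-disk text formats", {
  study <- small_study()
  dir <- file.path(tempdir(), "roundtrip_study")
  write_study(study, dir)
  back <- read_study(dir)
  expect_equal(back$gene_ranges, study$gene_ranges)
  expect_equal(back$snp_table, study$snp_table)
  expect_equal(back$arc_map, study$arc_map)
  expect_equal(back$ageing_like, study$ageing_like)
  expect_equal(back$pleio_like, study$pleio_like)
  expect_equal(unname(back$coexpr), unname(study$coexpr), tolerance = 1e-12)
  for (nm in names(study$layers)) {
    expect_equal(igraph::ecount(back$layers[[nm]]),
                 igraph::ecount(study$layers[[nm]]))
    expect_setequal(igraph::V(back$layers[[nm]])$name,
                    igraph::V(study$layers[[nm]])$name)
  }
  expect_error(read_study(file.path(tempdir(), "no_such_dir")), "missing")
})

test_that("planted expression architecture gives the intended Tau poles", {
  study <- small_study()
  tau <- compute_tau(study$expression)
  expect_true(all(tau[study$ageing_like] < 0.1))
  expect_true(all(tau[study$pleio_like] > 0.9))
})
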