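separable_table <- function(n = 200, n_pos = 30, noise = 0.01, seed = 1) {
  set.seed(seed)
  label <- c(rep(1L, n_pos), rep(0L, n - n_pos))
  data.frame(
    gene = sprintf("g%03d", seq_len(n)),
    label = label,
    f1 = label + rnorm(n, sd = noise),
    f2 = rnorm(n),
    stringsAsFactors = FALSE
  )
}

test_that("the configured dataset grid enumerates 47 dataset specifications", {
  g <- dataset_grid()
  expect_equal(nrow(g), 47)
  expect_equal(anyDuplicated(g$dataset_id), 0)
  expect_equal(sum(g$type == "metric_network"), 32)
  expect_equal(sum(g$type == "per_network"), 8)
  expect_equal(sum(g$type == "per_metric"), 6)
  expect_equal(sum(g$type == "multiplex_rwr"), 1)
})

test_that("feature widths follow the cluster and disease target counts", {
  study <- default_study()
  assoc <- study_assoc(study)
  store <- compute_feature_store(study$layers["PPI"], assoc,
                                 modes = c("ARC", "ARD"),
                                 multiplex_modes = character(0))
  spec_arc <- list(type = "metric_network", network = "PPI",
                   metric = "proximity_shortest", mode = "ARC")
  tab_arc <- build_feature_table(store, spec_arc, study$ageing_like)
  expect_equal(ncol(tab_arc) - 2, 8) # 8 cluster features besides gene + label

  spec_ard <- list(type = "metric_network", network = "PPI",
                   metric = "neighbour_counts", mode = "ARD")
  tab_ard <- build_feature_table(store, spec_ard, study$ageing_like)
  expect_equal(ncol(tab_ard) - 2, 57)
  expect_error(build_feature_table(store, spec_ard, character(0)), "empty")
})

test_that("per-metric aggregation stacks 8 features per network plus presence flags", {
  study <- small_study()
  assoc <- study_assoc(study)
  store <- compute_feature_store(study$layers, assoc, modes = "ARC",
                                 multiplex_modes = character(0))
  spec <- list(type = "per_metric", network = "all",
               metric = "proximity_average", mode = "ARC")
  tab <- build_feature_table(store, spec, study$ageing_like)
  n_arcs <- study$config$n_arcs
  expect_equal(ncol(tab) - 2, n_arcs * 4 + 4) # 4 layers + presence indicators
  # union coverage: every layer's genes are present
  union_genes <- sort(unique(unlist(lapply(study$layers,
                                           function(l) igraph::V(l)$name))))
  expect_setequal(tab$gene, union_genes)
  # a gene absent from COX95 has zero features and a zero indicator there
  absent <- setdiff(union_genes, igraph::V(study$layers$COX95)$name)[1]
  row <- tab[tab$gene == absent, ]
  expect_equal(row$present.COX95, 0)
  cox_cols <- grep("^COX95\\.prox", names(tab))
  expect_true(all(row[, cox_cols] == 0))
})

test_that("perfectly separable features give AUC 1 and random features AUC ~ 0.5", {
  tab <- separable_table()
  ev <- evaluate_classifier(tab, outer_folds = 5, inner_folds = 2,
                            n_trees = 100, seed = 4)
  expect_equal(ev$auc, 1)

  set.seed(5)
  null_tab <- separable_table(n = 400, n_pos = 80)
  null_tab$f1 <- rnorm(400) # break the signal
  aucs <- vapply(1:3, function(s) {
    evaluate_classifier(null_tab, outer_folds = 5, inner_folds = 2,
                        n_trees = 100, seed = s)$auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.06)
})

test_that("nested cross-validation keeps out-of-fold discipline and determinism", {
  tab <- separable_table(n = 150, n_pos = 25, noise = 0.5, seed = 2)
  ev1 <- evaluate_classifier(tab, outer_folds = 4, inner_folds = 2,
                             n_trees = 50, seed = 11)
  ev2 <- evaluate_classifier(tab, outer_folds = 4, inner_folds = 2,
                             n_trees = 50, seed = 11)
  expect_identical(ev1$scores, ev2$scores)
  expect_true(all(!is.na(ev1$scores)))
  # stratified outer folds partition every gene exactly once
  expect_equal(sort(unique(ev1$fold)), 1:4)
  expect_equal(length(ev1$fold), nrow(tab))
  # each fold holds positives (stratification)
  pos_per_fold <- table(ev1$fold[tab$label == 1])
  expect_true(all(pos_per_fold >= 1))
  expect_error(evaluate_classifier(transform(tab, label = 0)), "both classes")
})

test_that("the rank AUC agrees with an independent ROC implementation", {
  set.seed(21)
  scores <- c(rnorm(40, 1), rnorm(60))
  labels <- c(rep(1, 40), rep(0, 60))
  got <- pleionet:::auc_rank(scores, labels)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(got, ref, tolerance = 1e-12)
})

test_that("candidate ranking filters, sorts and breaks ties deterministically", {
  scores <- c(a = 0.9, b = 0.4, c = 0.9, d = 0.95, e = 0.6, f = 0.2)
  out <- rank_candidates(scores, positives = "d", threshold = 0.5, top_k = 2)
  expect_equal(out$gene, c("a", "c")) # tie at 0.9 broken lexicographically
  none <- rank_candidates(c(a = 0.1, b = 0.3), positives = character(0))
  expect_equal(nrow(none), 0)
})

test_that("held-out planted positives are recovered among the top candidates", {
  study <- default_study()
  assoc <- study_assoc(study)
  store <- compute_feature_store(study$layers, assoc, modes = character(0),
                                 multiplex_modes = "ARD")
  spec <- list(type = "multiplex_rwr", network = "multiplex",
               metric = "rwr", mode = "ARD")
  set.seed(77)
  hidden <- sample(study$ageing_like, 10)
  positives <- setdiff(study$ageing_like, hidden)
  tab <- build_feature_table(store, spec, positives)
  ev <- evaluate_classifier(tab, outer_folds = 5, inner_folds = 2,
                            n_trees = 100, seed = 77)
  top <- rank_candidates(ev$scores, positives, top_k = 30)
  k <- sum(hidden %in% top$gene)
  # hypergeometric check against a uniform ranking of non-positives
  n_cand <- nrow(tab) - length(positives)
  p_hyper <- phyper(k - 1, length(hidden), n_cand - length(hidden),
                    30, lower.tail = FALSE)
  expect_gte(k, 5)
  expect_lt(p_hyper, 1e-4)
})
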