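#' Pipeline configuration
#'
#' Collects every tunable of an end-to-end run: either a [study_config()] for
#' synthetic mode or an input directory of study files (never both), the
#' SNP-to-gene flank, the coexpression cutoffs, the random-walk settings, the
#' permutation budget and declared Bonferroni family, and the classifier
#' settings. The global seed is propagated to every stochastic stage.
#'
#' @param study a [study_config()] (synthetic mode), or `NULL`.
#' @param input_dir directory of study files as written by [write_study()]
#'   (real-data mode), or `NULL`.
#' @param out_dir output directory for stage files and the manifest.
#' @param flank SNP-to-gene flank in base pairs.
#' @param cox_cutoffs absolute-correlation thresholds for the two coexpression
#'   layers.
#' @param rwr an [rwr_config()].
#' @param n_perm permutations per test.
#' @param family_size declared Bonferroni family for the permutation table
#'   (the group-by-network family; 16 for four groups across four networks).
#' @param ml list of classifier settings: `datasets` (dataset ids from
#'   [dataset_grid()] to evaluate), `outer_folds`, `inner_folds`, `n_trees`.
#' @param seed global seed.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(study = study_config(),
                            input_dir = NULL,
                            out_dir = tempfile("pleionet_run_"),
                            flank = 10000,
                            cox_cutoffs = c(0.90, 0.95),
                            rwr = rwr_config(),
                            n_perm = 10000L,
                            family_size = 16L,
                            ml = list(),
                            seed = 42L) {
  if (!is.null(study) && !is.null(input_dir)) {
    stop("supply either a synthetic study config or an input directory, not both",
         call. = FALSE)
  }
  if (is.null(study) && is.null(input_dir)) {
    stop("one of study or input_dir is required", call. = FALSE)
  }
  ml_defaults <- list(datasets = "multiplex_rwr__multiplex__rwr__ARD",
                      outer_folds = 10L, inner_folds = 5L, n_trees = 500L)
  ml_defaults[names(ml)] <- ml
  structure(list(study = study, input_dir = input_dir, out_dir = out_dir,
                 flank = flank, cox_cutoffs = cox_cutoffs, rwr = rwr,
                 n_perm = as.integer(n_perm), family_size = as.integer(family_size),
                 ml = ml_defaults, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order — association mapping, network-layer
#' summaries, neighbour/proximity metrics, random walks, coexpression
#' coherence, tissue specificity, pathway-hierarchy positioning, permutation
#' tests, and classifier evaluation — writing each stage's outputs under
#' `config$out_dir` and recording every file (with md5 hash), the seed, and
#' per-stage record counts in a run manifest (`manifest.json`). Reruns with
#' the same configuration and seed are bit-identical for deterministic stages.
#'
#' @param config a [pipeline_config()].
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = config$seed, stages = list())
  note <- function(stage, files, records) {
    manifest$stages[[stage]] <<- list(
      files = as.character(files),
      md5 = unname(tools::md5sum(as.character(files))),
      records = records
    )
  }

  ## inputs
  if (!is.null(config$study)) {
    study <- generate_study(config$study)
    input_files <- write_study(study, file.path(out, "inputs"))
  } else {
    study <- read_study(config$input_dir)
    input_files <- list.files(config$input_dir, recursive = TRUE, full.names = TRUE)
  }
  manifest$inputs <- list(files = as.character(input_files),
                          md5 = unname(tools::md5sum(as.character(input_files))))
  layers <- study$layers

  ## stage 1: association mapping
  assoc <- map_snps_to_genes(study$snp_table, study$gene_ranges,
                             flank = config$flank, arc_map = study$arc_map)
  pleio <- compute_pleiotropy(assoc)
  f <- c(file.path(out, "associations_ard.tsv"),
         file.path(out, "associations_arc.tsv"),
         file.path(out, "pleiotropy.tsv"))
  write_tsv(assoc$ard, f[1]); write_tsv(assoc$arc, f[2]); write_tsv(pleio, f[3])
  note("map", f, nrow(assoc$ard))

  ## stage 2: layer summaries
  sets <- list(ageing_like = study$ageing_like, pleio_like = study$pleio_like,
               diseases = unique(assoc$ard$gene))
  summaries <- lapply(layers, layer_summary, sets = sets)
  f <- file.path(out, "layer_summaries.json")
  jsonlite::write_json(summaries, f, auto_unbox = TRUE, pretty = TRUE)
  note("layers", f, length(layers))

  ## stage 3: neighbour and proximity metrics (long format)
  metric_rows <- list()
  for (nm in names(layers)) {
    counts <- count_arc_interactions(layers[[nm]], assoc, level = "arc")
    prox <- trait_proximity_matrix(layers[[nm]], assoc, level = "arc",
                                   metric = "shortest")
    metric_rows[[nm]] <- rbind(
      data.frame(gene = names(counts), layer = nm, target = "any",
                 metric = "arc_interactions", value = as.numeric(counts)),
      data.frame(gene = rep(rownames(prox), ncol(prox)), layer = nm,
                 target = rep(colnames(prox), each = nrow(prox)),
                 metric = "proximity_shortest", value = as.vector(prox))
    )
  }
  metrics_long <- do.call(rbind, metric_rows)
  f <- file.path(out, "network_metrics.tsv")
  write_tsv(metrics_long, f)
  note("metrics", f, nrow(metrics_long))

  ## stage 4: random walks (cluster-seeded, per layer)
  f <- character(0)
  for (nm in names(layers)) {
    sc <- run_rwr_battery(layers[[nm]], assoc, level = "arc", config = config$rwr)
    std <- standardize_scores(sc)
    fi <- file.path(out, sprintf("rwr_%s_arc.tsv", nm))
    write_matrix_tsv(std$z, fi)
    f <- c(f, fi)
  }
  note("rwr", f, length(f))

  ## stage 5: coexpression coherence
  groups <- c(list(ageing_like = study$ageing_like, pleio_like = study$pleio_like),
              trait_gene_sets(assoc, "arc"))
  cx <- coexpression_set_matrix(study$coexpr, groups)
  f <- file.path(out, "coexpression_groups.tsv")
  write_matrix_tsv(cx, f)
  note("coexpr", f, nrow(cx))

  ## stage 6: tissue specificity
  tau <- compute_tau(study$expression)
  f <- file.path(out, "tau.tsv")
  write_tsv(data.frame(gene = names(tau), tau = unname(tau)), f)
  note("tau", f, length(tau))

  ## stage 7: pathway hierarchy
  hier <- hierarchy_distances(study$kegg_dag)
  f <- file.path(out, "hierarchy.tsv")
  write_tsv(hier, f)
  note("hierarchy", f, nrow(hier))

  ## stage 8: permutation tests (size-matched nulls)
  perms <- list()
  for (nm in intersect(c("PPI", "KEGG"), names(layers))) {
    counts <- count_arc_interactions(layers[[nm]], assoc, level = "arc")
    for (set_nm in c("ageing_like", "pleio_like")) {
      set <- intersect(sets[[set_nm]], names(counts))
      if (length(set) < 2) next
      perms[[sprintf("arc_interactions.%s.%s", nm, set_nm)]] <-
        permutation_null_mean(counts, set, n_perm = config$n_perm,
                              seed = config$seed,
                              family_size = config$family_size,
                              label = sprintf("arc_interactions %s %s", nm, set_nm))
    }
  }
  for (set_nm in c("ageing_like", "pleio_like")) {
    set <- intersect(sets[[set_nm]], names(tau))
    perms[[sprintf("tau.%s", set_nm)]] <-
      permutation_null_mean(tau, set, n_perm = config$n_perm,
                            seed = config$seed, family_size = config$family_size,
                            label = sprintf("tau %s", set_nm))
  }
  leaf <- stats::setNames(hier$leaf_mean, hier$gene)
  leaf <- leaf[is.finite(leaf)]
  pleio_in_dag <- intersect(study$pleio_like, names(leaf))
  if (length(pleio_in_dag) >= 2) {
    perms[["leaf_mean.pleio_like"]] <-
      permutation_null_mean(leaf, pleio_in_dag, n_perm = config$n_perm,
                            seed = config$seed, family_size = config$family_size,
                            label = "leaf_mean pleio_like")
  }
  perm_table <- permutation_table(perms)
  perm_table$min_p <- 1 / (config$n_perm + 1)
  perm_table$reduced_precision <- config$n_perm < 10000L
  f <- file.path(out, "permutation_tests.tsv")
  write_tsv(perm_table, f)
  note("permute", f, nrow(perm_table))

  ## stage 9: classifier
  grid <- dataset_grid(networks = names(layers))
  wanted <- grid[grid$dataset_id %in% config$ml$datasets, , drop = FALSE]
  if (nrow(wanted) == 0) stop("no configured ml dataset matches the grid", call. = FALSE)
  modes <- unique(wanted$mode[wanted$type != "multiplex_rwr"])
  mx_modes <- unique(wanted$mode[wanted$type == "multiplex_rwr"])
  store <- compute_feature_store(layers, assoc, modes = modes,
                                 config = config$rwr, multiplex_modes = mx_modes)
  positives <- study$ageing_like
  auc_rows <- list(); f <- character(0)
  for (i in seq_len(nrow(wanted))) {
    spec <- wanted[i, ]
    tab <- build_feature_table(store, spec, positives)
    ev <- evaluate_classifier(tab, outer_folds = config$ml$outer_folds,
                              inner_folds = config$ml$inner_folds,
                              n_trees = config$ml$n_trees, seed = config$seed)
    auc_rows[[spec$dataset_id]] <- data.frame(dataset_id = spec$dataset_id,
                                              n_genes = nrow(tab),
                                              n_positive = sum(tab$label),
                                              auc = ev$auc)
    fs <- file.path(out, sprintf("ml_scores_%s.tsv", spec$dataset_id))
    write_tsv(data.frame(gene = names(ev$scores), score = unname(ev$scores),
                         label = tab$label), fs)
    fc <- file.path(out, sprintf("ml_candidates_%s.tsv", spec$dataset_id))
    write_tsv(rank_candidates(ev$scores, positives), fc)
    f <- c(f, fs, fc)
  }
  fa <- file.path(out, "ml_auc.tsv")
  write_tsv(do.call(rbind, auc_rows), fa)
  note("ml", c(fa, f), nrow(wanted))

  manifest_file <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, manifest_file, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(manifest)
}
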