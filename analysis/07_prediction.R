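#!/usr/bin/env Rscript
# Stage 7: predict the planted ageing-like set from network-derived features
# with a balanced random forest under nested cross-validation, and rank novel
# candidates above the 0.5 decision threshold.
#
# The full grid holds 47 datasets; this driver evaluates a representative
# subset (the multiplex diffusion dataset plus two single-layer datasets) and
# writes their AUCs, out-of-fold scores, and top candidates.

library(pleionet)

study <- read_study("results/study")
assoc <- map_snps_to_genes(study$snp_table, study$gene_ranges,
                           arc_map = study$arc_map)

grid <- dataset_grid()
message("configured dataset grid: ", nrow(grid), " datasets")

wanted <- rbind(
  grid[grid$type == "multiplex_rwr", ],
  grid[grid$dataset_id == "metric_network__PPI__rwr__ARD", ],
  grid[grid$dataset_id == "metric_network__PPI__proximity_average__ARC", ]
)
store <- compute_feature_store(study$layers, assoc, modes = unique(wanted$mode),
                               multiplex_modes = "ARD")

rows <- list()
for (i in seq_len(nrow(wanted))) {
  spec <- wanted[i, ]
  tab <- build_feature_table(store, spec, study$ageing_like)
  ev <- evaluate_classifier(tab, outer_folds = 10, inner_folds = 5,
                            n_trees = 500, seed = 42)
  rows[[spec$dataset_id]] <- data.frame(dataset_id = spec$dataset_id,
                                        n_genes = nrow(tab), auc = ev$auc)
  cand <- rank_candidates(ev$scores, study$ageing_like)
  write.table(cand, sprintf("results/candidates_%s.tsv", spec$dataset_id),
              sep = "\t", quote = FALSE, row.names = FALSE)
  message(sprintf("  %-48s AUC %.3f (%d genes, %d candidates > 0.5)",
                  spec$dataset_id, ev$auc, nrow(tab), nrow(cand)))
}
write.table(do.call(rbind, rows), "results/ml_auc.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
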