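#!/usr/bin/env Rscript
# Stage 5: coexpression coherence within and between gene groups, and the Tau
# tissue-specificity contrast between the planted sets.

library(pleionet)

study <- read_study("results/study")
assoc <- map_snps_to_genes(study$snp_table, study$gene_ranges,
                           arc_map = study$arc_map)

groups <- c(list(ageing_like = study$ageing_like,
                 pleio_like = study$pleio_like),
            split(assoc$arc$gene, assoc$arc$arc_id))
cx <- coexpression_set_matrix(study$coexpr, groups)
write.table(data.frame(group = rownames(cx), cx, check.names = FALSE),
            "results/coexpression_groups.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("intra-set coexpression: ageing-like %.3f, pleiotropic-like %.3f",
                cx["ageing_like", "ageing_like"], cx["pleio_like", "pleio_like"]))

tau <- compute_tau(study$expression)
write.table(data.frame(gene = names(tau), tau = unname(tau)),
            "results/tau.tsv", sep = "\t", quote = FALSE, row.names = FALSE)

tau_tests <- list(
  ageing_like = permutation_null_mean(tau, study$ageing_like, n_perm = 10000,
                                      seed = 42, family_size = 4),
  pleio_like = permutation_null_mean(tau, study$pleio_like, n_perm = 10000,
                                     seed = 42, family_size = 4)
)
tt <- permutation_table(tau_tests)
write.table(tt, "results/tau_permutations.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("mean Tau: ageing-like %.3f (null %.3f, p_adj %.2g); pleiotropic-like %.3f (null %.3f, p_adj %.2g)",
                tt$observed[1], tt$null_mean[1], tt$p_adj[1],
                tt$observed[2], tt$null_mean[2], tt$p_adj[2]))

pw <- pairwise_group_tests(tau, list(ageing_like = study$ageing_like,
                                     pleio_like = study$pleio_like))
message(sprintf("ageing vs pleiotropic Tau rank-sum p_adj = %.3g", pw$p_adj))
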