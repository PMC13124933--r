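#!/usr/bin/env Rscript
# Stage 4: random walk with restart (r = 0.7) seeded on each disease cluster,
# per layer and on the multiplex stack, with z-standardisation within each
# seed set.

library(pleionet)

study <- read_study("results/study")
assoc <- map_snps_to_genes(study$snp_table, study$gene_ranges,
                           arc_map = study$arc_map)
cfg <- rwr_config(r = 0.7)

for (nm in names(study$layers)) {
  sc <- run_rwr_battery(study$layers[[nm]], assoc, level = "arc", config = cfg)
  std <- standardize_scores(sc)
  out <- data.frame(gene = rownames(std$z), std$z, check.names = FALSE)
  write.table(out, sprintf("results/rwr_%s_arc_z.tsv", nm), sep = "\t",
              quote = FALSE, row.names = FALSE)
  ag <- intersect(study$ageing_like, std$summary$gene)
  message(sprintf("%-6s mean z of ageing-like genes across clusters: %6.3f",
                  nm, mean(std$summary$mean_z[std$summary$gene %in% ag])))
}

mx <- run_rwr_battery(study$layers, assoc, level = "arc", config = cfg)
std <- standardize_scores(mx)
write.table(data.frame(gene = rownames(std$z), std$z, check.names = FALSE),
            "results/rwr_multiplex_arc_z.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("multiplex mean z of ageing-like genes: %6.3f",
                mean(std$summary$mean_z[std$summary$gene %in% study$ageing_like])))
message(sprintf("multiplex mean z of pleiotropic-like genes: %6.3f",
                mean(std$summary$mean_z[std$summary$gene %in% study$pleio_like])))
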