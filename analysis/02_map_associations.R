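#!/usr/bin/env Rscript
# Stage 2: map significant SNPs to genes (gene body +/- 10 kb), aggregate
# disease associations into clusters, and profile direct pleiotropy.

library(pleionet)

study <- read_study("results/study")
assoc <- map_snps_to_genes(study$snp_table, study$gene_ranges,
                           flank = 10000, arc_map = study$arc_map)
print(assoc)

pleio <- compute_pleiotropy(assoc)
write.table(assoc$ard, "results/associations_ard.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(pleio, "results/pleiotropy.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

message("associated genes: ", nrow(pleio))
message("high cluster-pleiotropy genes (>= 4 clusters): ",
        sum(pleio$pleiotropy_class == "high"))
message("planted pleiotropic-like genes recovered as high: ",
        sum(study$pleio_like %in% pleio$gene[pleio$pleiotropy_class == "high"]),
        " / ", length(study$pleio_like))
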