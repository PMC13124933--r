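#!/usr/bin/env Rscript
# Stage 1: generate the default synthetic study and write its input files.
#
# The study plants two gene sets with opposite architecture on a 1,000-gene
# universe (57 diseases in 8 clusters, 30 tissues): an "ageing-like" set that
# is broadly connected to disease genes and broadly expressed, and a
# "pleiotropic-like" set that is directly associated with >= 4 disease
# clusters but peripheral in every network and restricted to one tissue.

library(pleionet)

cfg <- study_config(seed = 42)
print(cfg)

study <- generate_study(cfg)
print(study)

files <- write_study(study, "results/study")
message("wrote ", length(files), " input files under results/study/")
message("planted ageing-like genes: ", length(study$ageing_like),
        "; pleiotropic-like genes: ", length(study$pleio_like))
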