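#!/usr/bin/env Rscript
# Stage 1: generate the synthetic multi-generation dataset.
#
# Emulates the five sequenced groups of the stress/recovery/re-exposure
# design (CK, S, P1S-P2CK, P1S-P3CK, P1S-P4S; 3 replicates each) with
# planted transcriptional-memory gene classes, plus replicate trait tables
# with weaken/strengthen reaction norms. Ground truth is written alongside
# so later stages can be scored.

library(clonemem)

outdir <- "results/data"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = 1)
print(cfg)

sim <- simulate_counts(cfg)
tra <- simulate_traits(cfg)

write_counts(sim$counts, file.path(outdir, "counts.tsv"))
write.csv(sim$samples, file.path(outdir, "samples.csv"), row.names = FALSE)
write.csv(tra$traits, file.path(outdir, "traits.csv"), row.names = FALSE)
write.csv(sim$truth, file.path(outdir, "truth_genes.csv"), row.names = FALSE)
write.csv(tra$truth, file.path(outdir, "truth_traits.csv"), row.names = FALSE)

cat("planted classes:\n")
print(table(sim$truth$class))
cat("wrote", nrow(sim$counts), "x", ncol(sim$counts), "counts to", outdir, "\n")
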