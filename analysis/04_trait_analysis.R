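#!/usr/bin/env Rscript
# Stage 4: trait statistics. Fisher's LSD across the P4 groups and
# classification of each trait's reaction norm as weaken (stress-induced
# suppression attenuated in the primed lineage) or strengthen
# (stress-induced rise amplified in the primed lineage).

library(clonemem)

traits <- read_traits("results/data/traits.csv")

dir.create("results/traits", showWarnings = FALSE, recursive = TRUE)
lsd_rows <- do.call(rbind, lapply(unique(traits$trait), function(tr) {
  p4 <- traits[traits$stage == "P4" & traits$trait == tr, ]
  res <- lsd_test(p4)
  cbind(trait = tr, res$pairs, f_stat = res$f_stat, f_p = res$f_p)
}))
write.csv(lsd_rows, "results/traits/lsd_p4.csv", row.names = FALSE)

cls <- classify_traits(traits)
write.csv(cls, "results/traits/trait_classification.csv", row.names = FALSE)
print(cls)

truth <- read.csv("results/data/truth_traits.csv")
merged <- merge(cls, truth, by = "trait")
hits <- with(merged, sum(label == class | (class == "none" &
                                           label == "unclassified")))
cat(sprintf("trait classes recovered: %d / %d\n", hits, nrow(merged)))
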