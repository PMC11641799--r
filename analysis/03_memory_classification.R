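#!/usr/bin/env Rscript
# Stage 3: three-step transcriptional-memory identification. Genes
# responding in the same direction under stress (P1) and on re-exposure
# (P4) are robust responders; those persisting through the first recovery
# generation are TMG2, and through the second as well, TMG3. The remaining
# genes fall into the transient / fluctuating / non-responsive taxonomy.

library(clonemem)

de <- lapply(c(P1 = "P1", P2 = "P2", P3 = "P3", P4 = "P4"), function(nm) {
  tab <- read.delim(file.path("results/de", paste0("de_", nm, ".tsv")))
  contrast_from_table(tab, contrast_name = nm)
})

dirs <- direction_table(de)
cls <- classify_patterns(dirs)
s <- summary(cls)

dir.create("results/memory", showWarnings = FALSE, recursive = TRUE)
write.csv(as.data.frame(cls), "results/memory/memory_classification.csv",
          row.names = FALSE)
for (lab in names(s$label_counts)) {
  ids <- cls$gene_id[cls$label == lab]
  writeLines(ids, file.path("results/memory", paste0(gsub("[^A-Za-z0-9]", "_",
                                                          lab), "_genes.txt")))
}

cat("pattern classes:\n")
print(unlist(s$label_counts))
cat(sprintf("TMG2: %d (%d up / %d down), of which TMG3: %d (%d up / %d down)\n",
            s$tmg2_up + s$tmg2_down, s$tmg2_up, s$tmg2_down,
            s$tmg3_up + s$tmg3_down, s$tmg3_up, s$tmg3_down))

# scoring against the planted truth, available in simulation mode
truth <- read.csv("results/data/truth_genes.csv")
planted <- truth$gene_id[truth$class %in%
  c("tmg3_up", "tmg3_down", "tmg2_only_up", "tmg2_only_down")]
tmg2 <- cls$gene_id[cls$label %in% c("TMG3", "TMG2-only")]
cat(sprintf("recovery vs truth: sensitivity %.3f, FDR %.3f\n",
            mean(planted %in% tmg2), mean(!(tmg2 %in% planted))))
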