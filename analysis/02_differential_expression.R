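#!/usr/bin/env Rscript
# Stage 2: differential expression of each generation against the P1
# control (CK) — median-of-ratios normalization, trend-floored
# method-of-moments dispersions, NB Wald test, BH adjustment, ternary
# calls at padj < 0.05 and |log2FC| > 0.5.

library(clonemem)

counts <- read_counts("results/data/counts.tsv")
samples <- read_samples("results/data/samples.csv")

contrasts <- run_contrasts(counts, samples)

dir.create("results/de", showWarnings = FALSE, recursive = TRUE)
for (nm in names(contrasts)) {
  x <- contrasts[[nm]]
  write_contrast(x, file.path("results/de", paste0("de_", nm, ".tsv")))
  cat(sprintf("%s (%s): %d up, %d down of %d genes\n",
              nm, attr(x, "contrast"), sum(x$direction == "up"),
              sum(x$direction == "down"), nrow(x)))
}
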