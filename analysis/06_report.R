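#!/usr/bin/env Rscript
# Stage 6: end-to-end run with the machine-readable report. Re-executes
# every stage from the same seed through run_pipeline() and writes the
# consolidated JSON report; its numbers match the per-stage outputs of
# scripts 01-05.

library(clonemem)

rep <- run_pipeline(sim_config(seed = 1), outdir = "results/run", quiet = FALSE)
print(rep)
cat("report written to results/run/report.json\n")
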