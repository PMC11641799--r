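#!/usr/bin/env Rscript
# Stage 5: weighted co-expression network on the DEG union. Soft threshold
# scan, unsigned adjacency at power 20, topological overlap, static-cut
# module detection with eigengene merging, module-trait association
# (PCC > 0.5, p < 0.05), top-30% edge filtering, top-10% hub genes, and
# the TMG share of weaken-/strengthen-related versus other modules.

library(clonemem)

counts <- read_counts("results/data/counts.tsv")
samples <- read_samples("results/data/samples.csv")
traits <- read_traits("results/data/traits.csv")
mem <- read.csv("results/memory/memory_classification.csv")
de <- lapply(c(P1 = "P1", P2 = "P2", P3 = "P3", P4 = "P4"), function(nm) {
  read.delim(file.path("results/de", paste0("de_", nm, ".tsv")))
})

deg_union <- unique(unlist(lapply(de, function(x) {
  x$gene_id[x$direction != "ns"]
})))
cat("DEG union:", length(deg_union), "genes\n")

sf <- size_factors(counts)
expr <- standardize_expression(sweep(counts[deg_union, ], 2, sf, "/"))

sft <- pick_soft_threshold(expr, powers = c(1, 2, 4, 6, 8, 12, 16, 20))
print(sft[, c("power", "sft_r2", "mean_k")])

net <- build_network(expr, power = 20, min_module_size = 30,
                     merge_cut = 0.25, edge_top = 0.30, hub_top = 0.10)
print(net)

trait_cls <- classify_traits(traits)
st <- sample_trait_matrix(traits, samples)
assoc <- module_trait_association(net$eigengenes, st,
                                  trait_classes = setNames(trait_cls$label,
                                                           trait_cls$trait))
mod_class <- setNames(assoc$module_class,
                      sub("^ME", "", names(assoc$module_class)))
enr <- tmg_module_enrichment(net$modules, mod_class, mem, hubs = net$hubs)

dir.create("results/network", showWarnings = FALSE, recursive = TRUE)
write.csv(data.frame(gene_id = names(net$modules), module = net$modules,
                     degree = net$degree[names(net$modules)], row.names = NULL),
          "results/network/modules.csv", row.names = FALSE)
write.table(net$edges, "results/network/edges.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.csv(data.frame(sample_id = rownames(net$eigengenes), net$eigengenes,
                     check.names = FALSE, row.names = NULL),
          "results/network/eigengenes.csv", row.names = FALSE)
write.csv(data.frame(module = rep(names(net$hubs), lengths(net$hubs)),
                     gene_id = unlist(net$hubs), row.names = NULL),
          "results/network/hub_genes.csv", row.names = FALSE)
write.csv(cbind(module = rownames(assoc$pcc), as.data.frame(assoc$pcc)),
          "results/network/module_trait_pcc.csv", row.names = FALSE)
jsonlite::write_json(list(fractions = enr$fractions, fisher_p = enr$fisher_p,
                          hub_tmg_percent = enr$hub_tmg_percent),
                     "results/network/tmg_enrichment.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

cat("module classes:\n"); print(mod_class)
cat("TMG share by module class (%):\n"); print(enr$fractions)
cat(sprintf("TMGs among hub genes: %.2f%%\n", enr$hub_tmg_percent))
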