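test_that("size factors recover scaling between samples", {
  # identical samples -> all factors 1
  m <- as_counts(c(10, 10), c(20, 20), c(5, 5))
  expect_equal(unname(size_factors(m)), c(1, 1))
  # second sample doubled -> (1/sqrt(2), sqrt(2)) after geometric-mean-1
  m2 <- as_counts(c(10, 20), c(40, 80), c(6, 12))
  expect_equal(unname(size_factors(m2)), c(1 / sqrt(2), sqrt(2)))
  # single informative gene: factors proportional to its counts
  m3 <- as_counts(c(10, 40), c(0, 7), c(3, 0))
  sf <- size_factors(m3)
  expect_equal(unname(sf[2] / sf[1]), 4)
  # no gene positive everywhere -> informative error
  m4 <- as_counts(c(0, 5), c(5, 0))
  expect_error(size_factors(m4), "filter")
})

test_that("method-of-moments dispersion is zero when variance equals mean", {
  # each group has values {1, 3}: mean 2, var 2 -> raw phi = 0
  m <- as_counts(rep(c(1L, 3L), 5), rep(c(1L, 3L), 5),
                 rep(c(2L, 6L), 5), rep(c(30L, 10L), 5))
  groups <- rep(c("a", "b", "c", "d", "e"), each = 2)
  ph <- estimate_dispersion(m, groups, sf = rep(1, 10))
  expect_equal(unname(attr(ph, "raw")[1:2]), c(0, 0))
  expect_error(estimate_dispersion(m, seq_len(10), sf = rep(1, 10)),
               "2 replicates")
})

test_that("dispersion estimates track the simulation truth", {
  withr::with_seed(11, {
    mu <- exp(runif(1000, log(20), log(2000)))
    pois <- matrix(rpois(1000 * 15, rep(mu, 15)), 1000, 15,
                   dimnames = list(sprintf("g%04d", 1:1000), NULL))
    colnames(pois) <- paste0("s", 1:15)
    mu2 <- exp(runif(2000, log(20), log(2000)))
    nb <- matrix(rnbinom(2000 * 12, mu = rep(mu2, 12), size = 1 / 0.2),
                 2000, 12, dimnames = list(sprintf("g%04d", 1:2000), NULL))
    colnames(nb) <- paste0("s", 1:12)
  })
  ph_pois <- estimate_dispersion(pois, rep(letters[1:5], each = 3),
                                 sf = rep(1, 15))
  expect_lte(median(ph_pois), 0.01)
  ph_nb <- estimate_dispersion(nb, rep(c("a", "b"), each = 6), sf = rep(1, 12))
  expect_gte(median(ph_nb), 0.1)
  expect_lte(median(ph_nb), 0.3)
})

test_that("identical groups give zero fold change and no calls", {
  m <- as_counts(c(10, 20, 30, 10, 20, 30), c(5, 5, 9, 5, 5, 9),
                 c(100, 90, 80, 100, 90, 80))
  groups <- rep(c("A", "B"), each = 3)
  res <- wald_test(m, groups, "A", "B", sf = rep(1, 6),
                   phi = rep(0.1, 3))
  expect_equal(res$log2fc, rep(0, 3))
  expect_true(all(res$direction == "ns"))
  expect_error(wald_test(m, groups, "A", "nope"), "unknown group")
})

test_that("swapping the groups negates fold changes and preserves p-values", {
  sim <- simulate_counts(sim_config(n_genes = 300, seed = 4,
                                    class_counts = c(tmg3_up = 30, tmg3_down = 30)))
  counts <- sim$counts[rowSums(sim$counts) > 0, ]
  sf <- size_factors(counts)
  phi <- estimate_dispersion(counts, sim$samples$group, sf)
  ab <- wald_test(counts, sim$samples, "CK", "S", sf = sf, phi = phi)
  ba <- wald_test(counts, sim$samples, "S", "CK", sf = sf, phi = phi)
  expect_equal(ba$log2fc, -ab$log2fc)
  expect_equal(ba$p_raw, ab$p_raw)
})

test_that("direction calls are invariant to rescaling one sample", {
  sim <- simulate_counts(sim_config(n_genes = 1500, seed = 9,
                                    class_counts = c(tmg3_up = 120, tmg3_down = 120,
                                                     transient = 80)))
  counts <- sim$counts
  scaled <- counts
  scaled[, 1] <- as.integer(round(scaled[, 1] * 2))
  dir1 <- run_contrasts(counts, sim$samples, quiet = TRUE)$P1$direction
  dir2 <- run_contrasts(scaled, sim$samples, quiet = TRUE)$P1$direction
  expect_gte(mean(dir1 == dir2), 0.99)
})

test_that("planted stress-responsive genes are detected in the P1 contrast", {
  sim <- simulate_counts(sim_config(seed = 21))
  res <- run_contrasts(sim$counts, sim$samples, quiet = TRUE)$P1
  up <- sim$truth$gene_id[sim$truth$class == "tmg3_up"]
  expect_gte(mean(res$direction[match(up, res$gene_id)] == "up"), 0.90)
})

test_that("BH adjustment matches the brute-force step-up rule", {
  # independent oracle: enumerate the step-up definition directly
  bh_brute <- function(p) {
    n <- length(p)
    adj <- numeric(n)
    for (i in seq_len(n)) {
      ge <- rank(p, ties.method = "first")[i]
      adj[i] <- min(1, min(sapply(which(rank(p, ties.method = "first") >= ge),
                                  function(j) p[j] * n / rank(p, ties.method = "first")[j])))
    }
    adj
  }
  for (s in 1:5) {
    p <- withr::with_seed(s, runif(sample(5:20, 1)))
    expect_equal(p.adjust(p, "BH"), bh_brute(p), tolerance = 1e-12)
  }
  # and the contract p_adj >= p_raw holds in pipeline output
  sim <- simulate_counts(sim_config(n_genes = 300, seed = 13,
                                    class_counts = c(tmg3_up = 30)))
  res <- run_contrasts(sim$counts, sim$samples, quiet = TRUE)$P2
  expect_true(all(res$p_adj >= res$p_raw - 1e-12))
})

test_that("an external DE table can replace the native engine", {
  tab <- data.frame(gene_id = c("a", "b", "c", "d"),
                    log2fc = c(2, -2, 0.2, 1),
                    p_adj = c(0.01, 0.001, 0.2, 0.9))
  res <- contrast_from_table(tab)
  expect_s3_class(res, "contrast_result")
  expect_equal(res$direction, c("up", "down", "ns", "ns"))
  expect_error(contrast_from_table(data.frame(gene_id = "a")), "columns")
})

test_that("native fold changes agree with DESeq2 on the same data", {
  sim <- simulate_counts(sim_config(n_genes = 400, seed = 17,
                                    class_counts = c(tmg3_up = 40, tmg3_down = 40)))
  counts <- sim$counts[rowSums(sim$counts) > 0, ]
  native <- run_contrasts(counts, sim$samples, quiet = TRUE)$P1
  suppressWarnings(suppressMessages({
    library(DESeq2)
    cold <- data.frame(grp = factor(sim$samples$group,
                                    levels = unique(sim$samples$group)))
    dds <- DESeqDataSetFromMatrix(counts, cold, ~grp)
    dds <- DESeq(dds, quiet = TRUE)
    ref <- results(dds, contrast = c("grp", "S", "CK"))
  }))
  shared <- intersect(native$gene_id, rownames(ref))
  lfc_n <- native$log2fc[match(shared, native$gene_id)]
  lfc_d <- ref$log2FoldChange[match(shared, rownames(ref))]
  expect_gte(cor(lfc_n, lfc_d), 0.95)
  # direction calls via the adapter agree on the vast majority of genes
  ext <- contrast_from_table(data.frame(gene_id = rownames(ref),
                                        log2fc = ref$log2FoldChange,
                                        p_adj = ifelse(is.na(ref$padj), 1, ref$padj)))
  agree <- mean(native$direction[match(shared, native$gene_id)] ==
                ext$direction[match(shared, ext$gene_id)])
  expect_gte(agree, 0.85)
})
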