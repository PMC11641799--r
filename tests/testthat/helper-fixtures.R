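# shared fixtures and independent oracles used across test files

# tiny count matrix with explicit values; samples named s1..sn
as_counts <- function(..., genes = NULL) {
  rows <- list(...)
  m <- do.call(rbind, rows)
  rownames(m) <- if (is.null(genes)) sprintf("g%02d", seq_len(nrow(m))) else genes
  colnames(m) <- sprintf("s%d", seq_len(ncol(m)))
  storage.mode(m) <- "integer"
  m
}

# random ternary direction table
random_dirs <- function(n_genes, seed) {
  withr::with_seed(seed, {
    d <- matrix(sample(c("up", "down", "ns"), 4 * n_genes, replace = TRUE,
                       prob = c(0.25, 0.25, 0.5)), ncol = 4)
  })
  data.frame(gene_id = sprintf("g%04d", seq_len(n_genes)),
             d_P1 = d[, 1], d_P2 = d[, 2], d_P3 = d[, 3], d_P4 = d[, 4],
             stringsAsFactors = FALSE)
}

# independent brute-force enumeration of the memory sets: plain row-by-row
# set comprehension, no shared code with the package internals
oracle_memory_sets <- function(dirs) {
  robust <- character(0); tmg2 <- character(0); tmg3 <- character(0)
  labels <- character(nrow(dirs))
  for (i in seq_len(nrow(dirs))) {
    d <- c(dirs$d_P1[i], dirs$d_P2[i], dirs$d_P3[i], dirs$d_P4[i])
    g <- dirs$gene_id[i]
    is_rob <- d[1] != "ns" && d[1] == d[4]
    is_t2 <- is_rob && d[2] == d[1]
    is_t3 <- is_t2 && d[3] == d[1]
    if (is_rob) robust <- c(robust, g)
    if (is_t2) tmg2 <- c(tmg2, g)
    if (is_t3) tmg3 <- c(tmg3, g)
    n_de <- sum(d != "ns")
    labels[i] <-
      if (is_t3) "TMG3"
      else if (is_t2) "TMG2-only"
      else if (is_rob) "robust-responsive"
      else if (n_de == 1) "transient"
      else if (n_de >= 2 && any(d == "up") && any(d == "down")) "fluctuating"
      else "non-responsive"
  }
  list(robust = robust, tmg2 = tmg2, tmg3 = tmg3, labels = labels)
}

# textbook pooled-MSE LSD t and p for two groups within a k-group layout
oracle_lsd_pair <- function(groups_list, i, j) {
  k <- length(groups_list)
  ns <- lengths(groups_list)
  mse <- sum(vapply(groups_list, function(v) sum((v - mean(v))^2), numeric(1))) /
    (sum(ns) - k)
  se <- sqrt(mse * (1 / ns[i] + 1 / ns[j]))
  tstat <- (mean(groups_list[[i]]) - mean(groups_list[[j]])) / se
  p <- 2 * pt(-abs(tstat), sum(ns) - k)
  list(t = tstat, p = p, mse = mse, df = sum(ns) - k)
}

planted_tmg_ids <- function(truth) {
  truth$gene_id[truth$class %in% c("tmg3_up", "tmg3_down",
                                   "tmg2_only_up", "tmg2_only_down")]
}
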