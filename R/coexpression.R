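#' Standardize an expression matrix for network construction
#'
#' Applies `log2(x + 1)` (optional) and per-gene z-scoring after removing
#' genes with missing values in more than half the samples or with zero
#' variance; remaining missing values are imputed with the gene mean before
#' scaling.
#'
#' @param expr genes x samples numeric matrix (FPKM-like or normalized
#'   counts).
#' @param log2_transform apply log2(x+1) first (default TRUE).
#' @param max_missing_frac drop genes missing in more than this fraction of
#'   samples (default 0.5).
#' @return standardized matrix (per-gene mean 0, SD 1) with attribute
#'   `dropped` listing removed gene ids.
#' @export
standardize_expression <- function(expr, log2_transform = TRUE,
                                   max_missing_frac = 0.5) {
  if (!is.matrix(expr) || !is.numeric(expr)) stop("expr must be a numeric matrix")
  if (ncol(expr) < 4) stop("need at least 4 samples")
  if (log2_transform) {
    if (any(expr < 0, na.rm = TRUE)) stop("negative values with log2_transform = TRUE")
    expr <- log2(expr + 1)
  }
  miss <- rowMeans(is.na(expr))
  v <- apply(expr, 1, stats::var, na.rm = TRUE)
  keep <- miss <= max_missing_frac & !is.na(v) & v > 0
  dropped <- rownames(expr)[!keep]
  expr <- expr[keep, , drop = FALSE]
  if (nrow(expr) < 2) stop("fewer than 2 genes left after filtering")
  if (anyNA(expr)) {
    mu <- rowMeans(expr, na.rm = TRUE)
    idx <- which(is.na(expr), arr.ind = TRUE)
    expr[idx] <- mu[idx[, 1]]
  }
  out <- t(scale(t(expr)))
  attr(out, "dropped") <- dropped
  out
}

#' Scale-free topology fit across soft-thresholding powers
#'
#' For each power beta, builds the unsigned adjacency `|cor|^beta`, computes
#' connectivities `k_i`, bins them into 10 equal-occupancy bins, and
#' regresses the log10 empirical density of k on `log10 mean(k)` per bin
#' (equal-occupancy bins carry the distribution in their widths, so the
#' density, not the constant per-bin count, is regressed). The signed fit index
#' `-sign(slope) * R^2` is positive when the degree distribution decays
#' (scale-free-like).
#'
#' @param expr standardized genes x samples matrix (>= 10 genes).
#' @param powers integer powers to scan (default 1:20).
#' @return data.frame: power, sft_r2 (signed), slope, mean_k, median_k,
#'   max_k.
#' @export
pick_soft_threshold <- function(expr, powers = 1:20) {
  if (nrow(expr) < 10) stop("too few genes to bin the degree distribution (need >= 10)")
  cors <- abs(stats::cor(t(expr)))
  if (anyNA(cors)) stop("non-finite correlations; standardize/filter the matrix first")
  diag(cors) <- 0
  res <- lapply(powers, function(beta) {
    a <- cors^beta
    k <- rowSums(a)
    data.frame(power = beta, scale_free_fit(k), mean_k = mean(k),
               median_k = stats::median(k), max_k = max(k))
  })
  do.call(rbind, res)
}

scale_free_fit <- function(k, n_bins = 10) {
  if (stats::sd(k) == 0) return(data.frame(sft_r2 = NA_real_, slope = NA_real_))
  breaks <- unique(stats::quantile(k, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(breaks) < 3) return(data.frame(sft_r2 = NA_real_, slope = NA_real_))
  bin <- cut(k, breaks = breaks, include.lowest = TRUE)
  k_mean <- tapply(k, bin, mean)
  # equal-occupancy bins hold equal counts, so the degree distribution enters
  # through the empirical density (proportion per unit degree), not the count
  dens <- (as.vector(table(bin)) / length(k)) / diff(breaks)
  ok <- dens > 0 & k_mean > 0
  lk <- log10(k_mean[ok])
  fit <- stats::lm(log10(dens[ok]) ~ lk)
  r2 <- summary(fit)$r.squared
  slope <- stats::coef(fit)[2]
  data.frame(sft_r2 = -sign(slope) * r2, slope = unname(slope))
}

#' Topological overlap matrix from an adjacency matrix
#'
#' `tom_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with the
#' shared-neighbour sum over u distinct from i and j and `k_i = sum_u a_iu`;
#' diagonal 1. For adjacencies in \[0, 1\] the result is symmetric in
#' \[0, 1\].
#'
#' @param adj symmetric adjacency matrix with entries in \[0, 1\].
#' @return topological overlap matrix of the same dimension.
#' @export
tom_similarity <- function(adj) {
  if (!isSymmetric(unname(adj), tol = 1e-8)) stop("adjacency must be symmetric")
  if (any(adj < 0 | adj > 1)) stop("adjacency entries must lie in [0, 1]")
  a <- adj
  diag(a) <- 0
  k <- rowSums(a)
  l <- a %*% a                     # includes u = i and u = j terms, both 0
  num <- l + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adj)
  tom
}

#' Build a weighted co-expression network
#'
#' Unsigned adjacency `|cor|^power`, topological overlap, average-linkage
#' clustering of the TOM dissimilarity, module detection by a static tree
#' cut (the scanned cut height, from just below the tree top downward, that
#' yields the most modules of at least `min_module_size` genes),
#' iterative merging of modules whose eigengenes correlate at or above
#' `1 - merge_cut`, and edge filtering/hub detection on the retained graph.
#' Modules are labelled with WGCNA-style colors in decreasing size order;
#' unassigned genes are "grey".
#'
#' @param expr standardized genes x samples matrix.
#' @param power soft-thresholding power (default 20).
#' @param min_module_size smallest module size (default 30).
#' @param merge_cut eigengene dissimilarity below which modules merge
#'   (default 0.25, i.e. correlation >= 0.75).
#' @param edge_top fraction of edges kept, ranked by TOM weight
#'   (default 0.30).
#' @param hub_top fraction of each module's genes called hubs by filtered
#'   degree (default 0.10).
#' @param cut_start highest scanned fraction of the maximal merge height
#'   for the static cut (default 0.9999, i.e. just below the tree top).
#' @return object of class `coexpression_network`: list with `modules`
#'   (named color per gene), `adjacency`, `tom`, `dendro`, `eigengenes`
#'   (samples x modules), `var_explained`, `edges` (data.frame gene_a,
#'   gene_b, weight), `edge_threshold`, `degree`, `hubs` (named list per
#'   module), `power`, `cut_height`.
#' @export
build_network <- function(expr, power = 20, min_module_size = 30,
                          merge_cut = 0.25, edge_top = 0.30, hub_top = 0.10,
                          cut_start = 0.9999) {
  stopifnot(power >= 1, edge_top > 0, edge_top <= 1, hub_top > 0, hub_top <= 1)
  cors <- stats::cor(t(expr))
  if (anyNA(cors)) stop("non-finite correlations; standardize/filter the matrix first")
  adj <- abs(cors)^power
  tom <- tom_similarity(adj)
  diss <- 1 - tom
  dendro <- stats::hclust(stats::as.dist(diss), method = "average")

  # static cut at the height yielding the most modules of at least
  # min_module_size genes; ties resolved toward the highest cut (fewer
  # unassigned genes fall out near the top of the tree)
  hmax <- max(dendro$height)
  fracs <- c(0.9999, 0.999, 0.995, seq(0.99, 0.05, by = -0.01))
  fracs <- fracs[fracs <= cut_start + 1e-12]
  best_n <- -1L
  cut_height <- NA_real_
  assign <- rep(0L, nrow(expr))
  for (frac in fracs) {
    h <- frac * hmax
    cl <- stats::cutree(dendro, h = h)
    sizes <- table(cl)
    big <- names(sizes)[sizes >= min_module_size]
    if (length(big) > best_n) {
      best_n <- length(big)
      cut_height <- h
      assign <- ifelse(cl %in% as.integer(big), cl, 0L)
    }
  }
  names(assign) <- rownames(expr)

  # merge modules with highly correlated eigengenes
  assign <- merge_close_modules(expr, assign, merge_cut)
  modules <- color_labels(assign)

  me <- module_eigengenes(expr, modules)

  # edge filtering on TOM weight
  ut <- upper.tri(tom)
  w <- tom[ut]
  thr <- stats::quantile(w, probs = 1 - edge_top, names = FALSE)
  keep <- which(ut & tom >= thr, arr.ind = TRUE)
  edges <- data.frame(gene_a = rownames(tom)[keep[, 1]],
                      gene_b = rownames(tom)[keep[, 2]],
                      weight = tom[keep], stringsAsFactors = FALSE)
  degree <- stats::setNames(integer(nrow(expr)), rownames(expr))
  tb <- table(c(edges$gene_a, edges$gene_b))
  degree[names(tb)] <- as.integer(tb)
  strength <- stats::setNames(numeric(nrow(expr)), rownames(expr))
  for (col in c("gene_a", "gene_b")) {
    agg <- tapply(edges$weight, edges[[col]], sum)
    strength[names(agg)] <- strength[names(agg)] + agg
  }

  net <- list(modules = modules, adjacency = adj, tom = tom, dendro = dendro,
              eigengenes = me$eigengenes, var_explained = me$var_explained,
              edges = edges, edge_threshold = thr, degree = degree,
              strength = strength, power = power,
              min_module_size = min_module_size, merge_cut = merge_cut,
              edge_top = edge_top, hub_top = hub_top, cut_height = cut_height)
  class(net) <- "coexpression_network"
  net$hubs <- hub_genes(net, hub_top = hub_top)
  net
}

#' @export
print.coexpression_network <- function(x, ...) {
  sizes <- sort(table(x$modules), decreasing = TRUE)
  cat("co-expression network:", length(x$modules), "genes, power =",
      x$power, "\n")
  cat("modules:", paste(names(sizes), sizes, sep = "=", collapse = ", "), "\n")
  cat("filtered edges:", nrow(x$edges), sprintf("(top %.0f%%)", 100 * x$edge_top), "\n")
  invisible(x)
}

merge_close_modules <- function(expr, assign, merge_cut) {
  repeat {
    ids <- setdiff(unique(assign), 0L)
    if (length(ids) < 2) return(assign)
    me <- sapply(ids, function(m) {
      eigengene_of(expr[assign == m, , drop = FALSE])
    })
    cc <- stats::cor(me)
    diag(cc) <- -Inf
    best <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    if (max(cc) < 1 - merge_cut) return(assign)
    assign[assign == ids[best[2]]] <- ids[best[1]]
  }
}

# WGCNA-style color sequence, by decreasing module size; 0 -> grey
color_labels <- function(assign) {
  palette <- c("turquoise", "blue", "brown", "yellow", "green", "red",
               "black", "pink", "magenta", "purple", "greenyellow", "tan",
               "salmon", "cyan", "midnightblue", "lightcyan", "grey60",
               "lightgreen", "lightyellow", "royalblue", "darkred",
               "darkgreen", "darkturquoise", "darkgrey", "orange",
               "darkorange", "white", "skyblue", "saddlebrown", "steelblue")
  ids <- setdiff(unique(assign), 0L)
  sizes <- vapply(ids, function(m) sum(assign == m), integer(1))
  ord <- ids[order(-sizes, ids)]
  cols <- c(palette, paste0("module", seq_len(max(0, length(ord) - length(palette)))))
  map <- stats::setNames(cols[seq_along(ord)], ord)
  out <- rep("grey", length(assign))
  hit <- assign != 0L
  out[hit] <- map[as.character(assign[hit])]
  stats::setNames(out, names(assign))
}

eigengene_of <- function(sub) {
  centered <- sub - rowMeans(sub)
  sv <- svd(centered, nu = 0, nv = 1)
  e <- sv$v[, 1]
  profile <- colMeans(sub)
  if (stats::cor(e, profile) < 0) e <- -e
  e
}

#' Module eigengenes
#'
#' Per module, the first right-singular vector of the gene-centered module
#' submatrix gives one score per sample (the module's first principal
#' component). The sign is aligned so the eigengene correlates positively
#' with the module's average expression profile. The grey (unassigned) set
#' is skipped.
#'
#' @param expr standardized genes x samples matrix.
#' @param modules named module label per gene (colors; "grey" ignored).
#' @return list: `eigengenes` (samples x modules matrix, columns `ME<color>`)
#'   and `var_explained` (fraction of module variance captured).
#' @export
module_eigengenes <- function(expr, modules) {
  mods <- setdiff(unique(modules), "grey")
  if (length(mods) == 0) {
    return(list(eigengenes = matrix(numeric(0), nrow = ncol(expr), ncol = 0,
                                    dimnames = list(colnames(expr), NULL)),
                var_explained = numeric(0)))
  }
  me <- matrix(NA_real_, nrow = ncol(expr), ncol = length(mods),
               dimnames = list(colnames(expr), paste0("ME", mods)))
  ve <- stats::setNames(numeric(length(mods)), paste0("ME", mods))
  for (i in seq_along(mods)) {
    sub <- expr[modules == mods[i], , drop = FALSE]
    if (nrow(sub) < 2) stop("module '", mods[i], "' has fewer than 2 genes")
    centered <- sub - rowMeans(sub)
    sv <- svd(centered, nu = 0, nv = 1)
    e <- sv$v[, 1]
    if (stats::cor(e, colMeans(sub)) < 0) e <- -e
    me[, i] <- e
    ve[i] <- sv$d[1]^2 / sum(sv$d^2)
  }
  list(eigengenes = me, var_explained = ve)
}

#' Module-trait association
#'
#' Pearson correlation between each module eigengene and each trait across
#' samples, with a two-sided p-value from the t approximation on n - 2 df.
#' A module-trait pair is flagged significant when `PCC > 0.5` and
#' `p < 0.05`. When trait classes are supplied, modules are classed as
#' weaken-related / strengthen-related / other according to the traits they
#' are significantly associated with; a module hitting both classes is
#' assigned by its largest |PCC|.
#'
#' @param eigengenes samples x modules matrix (see [module_eigengenes()]).
#' @param sample_traits samples x traits numeric matrix aligned to the
#'   eigengene rows (e.g. group trait means mapped to RNA samples, see
#'   [sample_trait_matrix()]).
#' @param trait_classes optional named vector ("weaken"/"strengthen"/other)
#'   per trait.
#' @param pcc_threshold,p_threshold significance thresholds (defaults 0.5
#'   and 0.05).
#' @return list: `pcc` and `p` (modules x traits matrices), `significant`
#'   (logical matrix), `module_class` (named vector, when classes given).
#' @export
module_trait_association <- function(eigengenes, sample_traits,
                                     trait_classes = NULL,
                                     pcc_threshold = 0.5, p_threshold = 0.05) {
  sample_traits <- as.matrix(sample_traits)
  if (nrow(sample_traits) != nrow(eigengenes)) {
    stop("sample_traits rows must match eigengene rows (one per RNA sample)")
  }
  if (anyNA(sample_traits)) stop("trait missing for some samples")
  n <- nrow(eigengenes)
  pcc <- stats::cor(eigengenes, sample_traits)     # modules x traits
  tt <- pcc * sqrt((n - 2) / pmax(1 - pcc^2, 1e-12))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  sig <- pcc > pcc_threshold & p < p_threshold

  module_class <- NULL
  if (!is.null(trait_classes)) {
    module_class <- stats::setNames(rep("other", nrow(pcc)), rownames(pcc))
    for (m in rownames(pcc)) {
      hits <- colnames(pcc)[sig[m, ]]
      cls <- trait_classes[hits]
      cand <- unique(cls[cls %in% c("weaken", "strengthen")])
      if (length(cand) == 1) {
        module_class[m] <- paste0(cand, "-related")
      } else if (length(cand) > 1) {
        best <- hits[which.max(abs(pcc[m, hits]))]
        module_class[m] <- paste0(trait_classes[best], "-related")
      }
    }
  }
  list(pcc = pcc, p = p, significant = sig, module_class = module_class,
       n = n)
}

#' Map replicate trait measurements to RNA samples by group means
#'
#' Each RNA sample receives its sequenced group's mean trait value (the
#' trait replicates are not paired with RNA replicates, so the group mean is
#' the natural per-sample trait value for eigengene correlation).
#'
#' @param trait_table replicate trait table (see [simulate_traits()]).
#' @param samples RNA sample sheet with stage, lineage, condition.
#' @return samples x traits numeric matrix.
#' @export
sample_trait_matrix <- function(trait_table, samples) {
  tt <- as.data.frame(trait_table)
  traits <- unique(tt$trait)
  out <- matrix(NA_real_, nrow = nrow(samples), ncol = length(traits),
                dimnames = list(samples$sample_id, traits))
  for (tr in traits) {
    sub <- tt[tt$trait == tr, , drop = FALSE]
    key <- paste(sub$stage, sub$lineage, sub$condition)
    mns <- tapply(sub$value, key, mean)
    skey <- paste(samples$stage, samples$lineage, samples$condition)
    out[, tr] <- mns[skey]
  }
  if (anyNA(out)) {
    stop("trait table does not cover every RNA sample group")
  }
  out
}

#' Hub genes per module
#'
#' On the filtered edge graph, the top `ceil(hub_top * module size)` genes
#' of each module by degree are hubs; ties are broken by total incident
#' edge weight, then lexicographic gene id. The grey set is skipped.
#'
#' @param net a `coexpression_network`.
#' @param hub_top hub fraction (default from the network, 0.10).
#' @return named list of hub gene-id vectors, one per module.
#' @export
hub_genes <- function(net, hub_top = net$hub_top) {
  mods <- setdiff(unique(net$modules), "grey")
  out <- lapply(mods, function(m) {
    genes <- names(net$modules)[net$modules == m]
    if (length(genes) == 0) stop("empty module: ", m)
    n_hub <- ceiling(hub_top * length(genes))
    ord <- order(-net$degree[genes], -net$strength[genes], genes)
    genes[ord][seq_len(n_hub)]
  })
  stats::setNames(out, mods)
}

#' TMG share of trait-related modules
#'
#' Fraction of genes labeled TMG (TMG3 or TMG2-only) within the modules of
#' each class (weaken-related, strengthen-related, other), plus a 2x2
#' Fisher exact test of TMG membership in trait-related vs other modules.
#'
#' @param modules named module color per gene.
#' @param module_class named class per module color (see
#'   [module_trait_association()]).
#' @param memory a `memory_classification` data.frame sharing the gene
#'   universe.
#' @param hubs optional hub list; when given, the TMG share of all hub genes
#'   is reported too.
#' @return list: `fractions` (data.frame class, n_genes, n_tmg, fraction —
#'   fraction as a percentage), `fisher_p`, `table` (the 2x2 table),
#'   `hub_tmg_percent` (when hubs given).
#' @export
tmg_module_enrichment <- function(modules, module_class, memory, hubs = NULL) {
  is_tmg <- stats::setNames(memory$label %in% c("TMG3", "TMG2-only"),
                            memory$gene_id)
  genes <- intersect(names(modules), memory$gene_id)
  if (length(genes) == 0) stop("modules and memory classification share no genes")
  gmod <- modules[genes]
  gcls <- stats::setNames(rep("other", length(genes)), genes)
  known <- gmod %in% names(module_class)
  gcls[known] <- module_class[gmod[known]]
  gtmg <- is_tmg[genes]

  cls_levels <- c("weaken-related", "strengthen-related", "other")
  fr <- do.call(rbind, lapply(cls_levels, function(cl) {
    sel <- gcls == cl
    data.frame(class = cl, n_genes = sum(sel), n_tmg = sum(gtmg[sel]),
               fraction = if (sum(sel) > 0) 100 * sum(gtmg[sel]) / sum(sel)
                          else NA_real_,
               stringsAsFactors = FALSE)
  }))

  related <- gcls != "other"
  tab <- matrix(c(sum(gtmg & related), sum(!gtmg & related),
                  sum(gtmg & !related), sum(!gtmg & !related)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("trait-related", "other"),
                                c("TMG", "non-TMG")))
  fisher_p <- if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
    stats::fisher.test(tab)$p.value
  } else 1
  out <- list(fractions = fr, fisher_p = fisher_p, table = tab)
  if (!is.null(hubs)) {
    hub_ids <- intersect(unlist(hubs), genes)
    out$hub_tmg_percent <- if (length(hub_ids) > 0) {
      100 * mean(gtmg[hub_ids])
    } else NA_real_
  }
  out
}
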