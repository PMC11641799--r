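#' Median-of-ratios size factors
#'
#' Per-sample normalization factors computed as the median, over genes with
#' all-positive counts, of the ratio of the sample's count to the gene's
#' geometric mean across samples. Factors are rescaled to have geometric
#' mean 1 so that normalized counts stay on the count scale.
#'
#' @param counts non-negative integer matrix, genes x samples.
#' @return named numeric vector of positive size factors, one per sample.
#' @export
size_factors <- function(counts) {
  check_counts(counts)
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) {
    stop("no gene has positive counts in every sample; ",
         "filter low-count genes or samples before normalization")
  }
  lg <- log(counts[pos, , drop = FALSE])
  geo <- rowMeans(lg)
  sf <- apply(lg, 2, function(col) exp(stats::median(col - geo)))
  sf <- sf / exp(mean(log(sf)))
  stats::setNames(sf, colnames(counts))
}

#' Per-gene NB dispersion by method of moments with trend shrinkage
#'
#' For each gene, the raw dispersion is the pooled within-group
#' method-of-moments estimate on normalized counts,
#' `max(0, (v - m) / m^2)` combined across groups with df weights. A
#' log-linear mean-dispersion trend is then fitted across genes and used as
#' a floor: the returned dispersion is the larger of the gene-wise estimate
#' and the trend. At typical replicate numbers the gene-wise estimate is
#' extremely noisy and often truncates to zero; taking it below the trend
#' would understate the variance and inflate the Wald statistic, so
#' below-trend estimates are raised to the trend while above-trend
#' estimates are retained (the same protection DESeq2 applies when the
#' gene-wise dispersion falls under the fitted trend).
#'
#' @param counts genes x samples integer matrix.
#' @param groups factor/character of length `ncol(counts)` giving the group
#'   of each sample; every group must have at least 2 replicates.
#' @param sf size factors (default: [size_factors()]).
#' @return numeric vector of shrunken dispersions, with attributes `raw`
#'   (method-of-moments estimates) and `trend` (fitted trend values).
#' @export
estimate_dispersion <- function(counts, groups, sf = size_factors(counts)) {
  check_counts(counts)
  groups <- as.character(groups)
  if (length(groups) != ncol(counts)) stop("groups must match columns of counts")
  tab <- table(groups)
  if (any(tab < 2)) {
    stop("dispersion estimation needs >= 2 replicates per group; offending: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  }
  y <- sweep(counts, 2, sf, "/")
  idx <- split(seq_along(groups), groups)
  num <- 0; den <- 0
  grand <- rowMeans(y)
  for (ix in idx) {
    m <- rowMeans(y[, ix, drop = FALSE])
    v <- apply(y[, ix, drop = FALSE], 1, stats::var)
    w <- length(ix) - 1
    contrib <- (v - m) / pmax(m, 1e-8)^2
    num <- num + w * contrib
    den <- den + w
  }
  raw <- pmax(0, num / den)
  # log-linear trend of dispersion on mean expression
  floor_phi <- 1e-4
  ok <- raw > floor_phi & grand > 0
  if (sum(ok) >= 10) {
    lx <- log(grand[ok])
    fit <- stats::lm(log(raw[ok]) ~ lx)
    trend <- exp(cbind(1, log(pmax(grand, 1e-8))) %*% stats::coef(fit))[, 1]
  } else {
    trend <- rep(max(exp(mean(log(pmax(raw, floor_phi)))), floor_phi), length(raw))
  }
  trend <- pmin(pmax(trend, floor_phi), 10)
  shrunk <- pmax(raw, trend)
  shrunk <- stats::setNames(shrunk, rownames(counts))
  attr(shrunk, "raw") <- stats::setNames(raw, rownames(counts))
  attr(shrunk, "trend") <- stats::setNames(trend, rownames(counts))
  shrunk
}

#' Negative-binomial Wald test between two sample groups
#'
#' Per gene, group means of normalized counts define the fold change
#' `log2fc = log2(mean_B / mean_A)` (an all-zero group mean is floored at
#' 0.5 to keep the ratio finite). The delta-method standard error of the
#' log2 mean under the NB variance `m/s_j + phi * m^2` per sample yields a
#' Wald z statistic with a two-sided normal p-value; p-values are BH-adjusted
#' across genes and ternary direction calls are made at `p_adj < alpha` and
#' `|log2fc| > lfc_threshold`.
#'
#' @param counts genes x samples integer matrix.
#' @param samples data.frame with `sample_id` and `group` columns matching
#'   the matrix columns, or a character vector of group labels.
#' @param group_a,group_b labels of the reference (A) and test (B) group.
#' @param sf size factors; computed from the full matrix by default.
#' @param phi per-gene dispersions; estimated from the full matrix by
#'   default.
#' @param alpha adjusted-p significance threshold (default 0.05).
#' @param lfc_threshold absolute log2-fold-change threshold (default 0.5).
#' @param contrast_name label stored in the result.
#' @return data.frame of class `contrast_result`: gene_id, base_mean_a,
#'   base_mean_b, log2fc, se, stat, p_raw, p_adj, direction; attributes
#'   `size_factors`, `dispersions`, `contrast`, `alpha`, `lfc_threshold`.
#' @export
wald_test <- function(counts, samples, group_a, group_b,
                      sf = NULL, phi = NULL,
                      alpha = 0.05, lfc_threshold = 0.5,
                      contrast_name = paste(group_b, "vs", group_a)) {
  check_counts(counts)
  groups <- if (is.data.frame(samples)) samples$group else as.character(samples)
  if (length(groups) != ncol(counts)) stop("samples must match columns of counts")
  if (!group_a %in% groups) stop("unknown group label: ", group_a)
  if (!group_b %in% groups) stop("unknown group label: ", group_b)
  if (is.null(sf)) sf <- size_factors(counts)
  if (is.null(phi)) phi <- estimate_dispersion(counts, groups, sf)

  ia <- which(groups == group_a)
  ib <- which(groups == group_b)
  y <- sweep(counts, 2, sf, "/")
  ma <- rowMeans(y[, ia, drop = FALSE])
  mb <- rowMeans(y[, ib, drop = FALSE])
  ma_f <- ifelse(ma > 0, ma, 0.5)
  mb_f <- ifelse(mb > 0, mb, 0.5)
  log2fc <- log2(mb_f / ma_f)

  # delta-method variance of log2 of a mean of normalized NB counts
  var_log2_mean <- function(m, idx) {
    m_se <- pmax(m, 0.5)  # variance floor for empty groups
    v <- outer(m_se, 1 / sf[idx]) + phi * m_se^2
    rowSums(v) / (length(idx)^2 * (m_se * log(2))^2)
  }
  se <- sqrt(var_log2_mean(ma, ia) + var_log2_mean(mb, ib))
  stat <- log2fc / se
  p_raw <- 2 * stats::pnorm(-abs(stat))
  p_adj <- stats::p.adjust(p_raw, method = "BH")
  direction <- rep("ns", length(p_adj))
  direction[p_adj < alpha & log2fc > lfc_threshold] <- "up"
  direction[p_adj < alpha & log2fc < -lfc_threshold] <- "down"

  res <- data.frame(gene_id = rownames(counts),
                    base_mean_a = ma, base_mean_b = mb,
                    log2fc = log2fc, se = se, stat = stat,
                    p_raw = p_raw, p_adj = p_adj, direction = direction,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(res, "size_factors") <- sf
  attr(res, "dispersions") <- phi
  attr(res, "contrast") <- contrast_name
  attr(res, "alpha") <- alpha
  attr(res, "lfc_threshold") <- lfc_threshold
  class(res) <- c("contrast_result", "data.frame")
  res
}

#' Run the four generation contrasts against the P1 control
#'
#' Filters genes with zero counts in every sample (logged via message), then
#' tests each of the S, P1S-P2CK, P1S-P3CK and P1S-P4S groups against CK
#' with shared size factors and dispersions. Only five groups are sequenced
#' in this design, so the single P1 control serves as the reference for all
#' four stages.
#'
#' @inheritParams wald_test
#' @param samples sample sheet with `group` column (see [simulate_counts()]).
#' @param quiet suppress the dropped-gene message.
#' @return named list of `contrast_result` data.frames: P1, P2, P3, P4.
#' @export
run_contrasts <- function(counts, samples, alpha = 0.05, lfc_threshold = 0.5,
                          quiet = FALSE) {
  check_counts(counts)
  keep <- rowSums(counts) > 0
  if (!all(keep) && !quiet) {
    message(sum(!keep), " gene(s) with all-zero counts dropped before testing")
  }
  counts <- counts[keep, , drop = FALSE]
  sf <- size_factors(counts)
  phi <- estimate_dispersion(counts, samples$group, sf)
  contrasts <- c(P1 = "S", P2 = "P1S-P2CK", P3 = "P1S-P3CK", P4 = "P1S-P4S")
  out <- lapply(names(contrasts), function(nm) {
    wald_test(counts, samples, "CK", contrasts[[nm]], sf = sf, phi = phi,
              alpha = alpha, lfc_threshold = lfc_threshold,
              contrast_name = paste0(nm, ": ", contrasts[[nm]], " vs CK"))
  })
  stats::setNames(out, names(contrasts))
}

#' Adapt an externally produced DE table to a contrast result
#'
#' Users who ran another differential-expression tool can feed its output
#' into the memory classification: the table needs `gene_id`, `log2fc` and
#' `p_adj` columns; direction calls are recomputed at the given thresholds.
#'
#' @param tab data.frame with gene_id, log2fc, p_adj (optionally p_raw).
#' @inheritParams wald_test
#' @return a `contrast_result` data.frame.
#' @export
contrast_from_table <- function(tab, alpha = 0.05, lfc_threshold = 0.5,
                                contrast_name = "external") {
  need <- c("gene_id", "log2fc", "p_adj")
  if (!all(need %in% names(tab))) {
    stop("external DE table needs columns: ", paste(need, collapse = ", "))
  }
  direction <- rep("ns", nrow(tab))
  ok <- !is.na(tab$p_adj) & !is.na(tab$log2fc)
  direction[ok & tab$p_adj < alpha & tab$log2fc > lfc_threshold] <- "up"
  direction[ok & tab$p_adj < alpha & tab$log2fc < -lfc_threshold] <- "down"
  res <- data.frame(gene_id = as.character(tab$gene_id),
                    log2fc = tab$log2fc,
                    p_raw = if ("p_raw" %in% names(tab)) tab$p_raw else NA_real_,
                    p_adj = tab$p_adj, direction = direction,
                    stringsAsFactors = FALSE)
  attr(res, "contrast") <- contrast_name
  attr(res, "alpha") <- alpha
  attr(res, "lfc_threshold") <- lfc_threshold
  class(res) <- c("contrast_result", "data.frame")
  res
}

check_counts <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop("counts must be a numeric matrix (genes x samples)")
  }
  if (anyNA(counts) || any(!is.finite(counts))) stop("counts must be finite")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(abs(counts - round(counts)) > 1e-8)) stop("counts must be integers")
  if (!is.null(rownames(counts)) && anyDuplicated(rownames(counts))) {
    stop("duplicate gene ids")
  }
  if (!is.null(colnames(counts)) && anyDuplicated(colnames(counts))) {
    stop("duplicate sample ids")
  }
  invisible(TRUE)
}
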