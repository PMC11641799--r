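#' Direction table across the four generation contrasts
#'
#' Collects the ternary direction calls (up/down/ns) of the P1-P4 contrasts
#' into one row per gene. The gene universe is the intersection of genes
#' tested in all four contrasts; genes missing from any contrast are
#' excluded (and reported via message).
#'
#' @param contrasts named list of `contrast_result` data.frames with names
#'   P1, P2, P3, P4 (see [run_contrasts()]).
#' @param quiet suppress the dropped-gene message.
#' @return data.frame: gene_id, d_P1, d_P2, d_P3, d_P4.
#' @export
direction_table <- function(contrasts, quiet = FALSE) {
  need <- c("P1", "P2", "P3", "P4")
  if (!all(need %in% names(contrasts))) {
    stop("contrasts must be a named list with elements P1, P2, P3, P4")
  }
  ids <- Reduce(intersect, lapply(contrasts[need], function(x) x$gene_id))
  n_all <- length(unique(unlist(lapply(contrasts[need], function(x) x$gene_id))))
  if (length(ids) < n_all && !quiet) {
    message(n_all - length(ids),
            " gene(s) absent from at least one contrast excluded from the universe")
  }
  cols <- lapply(contrasts[need], function(x) {
    x$direction[match(ids, x$gene_id)]
  })
  out <- data.frame(gene_id = ids, d_P1 = cols$P1, d_P2 = cols$P2,
                    d_P3 = cols$P3, d_P4 = cols$P4, stringsAsFactors = FALSE)
  check_direction_table(out)
  out
}

check_direction_table <- function(dirs) {
  need <- c("gene_id", "d_P1", "d_P2", "d_P3", "d_P4")
  if (!all(need %in% names(dirs))) {
    stop("direction table needs columns: ", paste(need, collapse = ", "))
  }
  vals <- unlist(dirs[, c("d_P1", "d_P2", "d_P3", "d_P4")], use.names = FALSE)
  if (!all(vals %in% c("up", "down", "ns"))) {
    stop("directions must be 'up', 'down' or 'ns'")
  }
  if (anyDuplicated(dirs$gene_id)) stop("duplicate gene ids in direction table")
  invisible(TRUE)
}

#' Robust stress-responsive genes
#'
#' Genes differentially expressed in the same direction under the initial
#' stress (P1) and upon re-exposure (P4): the starting set for memory-gene
#' identification.
#'
#' @param dirs a direction table (see [direction_table()]).
#' @return data.frame: gene_id, sign (the shared direction).
#' @export
robust_responsive <- function(dirs) {
  check_direction_table(dirs)
  keep <- dirs$d_P1 == dirs$d_P4 & dirs$d_P1 != "ns"
  data.frame(gene_id = dirs$gene_id[keep], sign = dirs$d_P1[keep],
             stringsAsFactors = FALSE)
}

#' Second-generation transcriptional memory genes (TMG2)
#'
#' Robust responsive genes whose direction persists through the first
#' recovery generation (P2).
#'
#' @inheritParams robust_responsive
#' @return data.frame: gene_id, sign.
#' @export
identify_tmg2 <- function(dirs) {
  check_direction_table(dirs)
  rob <- robust_responsive(dirs)
  d2 <- dirs$d_P2[match(rob$gene_id, dirs$gene_id)]
  rob[d2 == rob$sign, , drop = FALSE]
}

#' Third-generation transcriptional memory genes (TMG3)
#'
#' TMG2 genes whose direction also persists through the second recovery
#' generation (P3); always a subset of TMG2.
#'
#' @inheritParams robust_responsive
#' @return data.frame: gene_id, sign.
#' @export
identify_tmg3 <- function(dirs) {
  check_direction_table(dirs)
  tmg2 <- identify_tmg2(dirs)
  d3 <- dirs$d_P3[match(tmg2$gene_id, dirs$gene_id)]
  tmg2[d3 == tmg2$sign, , drop = FALSE]
}

#' Classify expression patterns across the four contrasts
#'
#' Assigns each gene exactly one label, in priority order:
#' \describe{
#'   \item{TMG3}{memory persists through both recovery generations.}
#'   \item{TMG2-only}{memory through P2 but not P3.}
#'   \item{robust-responsive}{same direction at P1 and P4 but not through
#'     P2 (no memory carried across recovery).}
#'   \item{transient}{differentially expressed in exactly one contrast.}
#'   \item{fluctuating}{differentially expressed in two or more contrasts
#'     with conflicting signs, without being robust.}
#'   \item{non-responsive}{anything else (including same-sign multi-contrast
#'     patterns that are not robust at P1/P4).}
#' }
#' The sign is the shared direction for memory/robust labels, the single
#' direction for transient genes, "mixed" for fluctuating genes and "none"
#' otherwise.
#'
#' @inheritParams robust_responsive
#' @return data.frame: gene_id, label, sign, d_P1..d_P4.
#' @export
classify_patterns <- function(dirs) {
  check_direction_table(dirs)
  d <- as.matrix(dirs[, c("d_P1", "d_P2", "d_P3", "d_P4")])
  n_de <- rowSums(d != "ns")
  n_up <- rowSums(d == "up")
  n_down <- rowSums(d == "down")
  robust <- d[, 1] == d[, 4] & d[, 1] != "ns"
  tmg2 <- robust & d[, 2] == d[, 1]
  tmg3 <- tmg2 & d[, 3] == d[, 1]

  label <- rep("non-responsive", nrow(d))
  label[n_de >= 2 & n_up > 0 & n_down > 0 & !robust] <- "fluctuating"
  label[n_de == 1] <- "transient"
  label[robust] <- "robust-responsive"
  label[tmg2] <- "TMG2-only"
  label[tmg3] <- "TMG3"

  sign <- rep("none", nrow(d))
  sign[label == "fluctuating"] <- "mixed"
  single <- label == "transient"
  if (any(single)) {
    sign[single] <- apply(d[single, , drop = FALSE], 1,
                          function(r) r[r != "ns"][1])
  }
  memlab <- label %in% c("TMG3", "TMG2-only", "robust-responsive")
  sign[memlab] <- d[memlab, 1]

  out <- cbind(data.frame(gene_id = dirs$gene_id, label = label, sign = sign,
                          stringsAsFactors = FALSE),
               dirs[, c("d_P1", "d_P2", "d_P3", "d_P4")])
  class(out) <- c("memory_classification", "data.frame")
  out
}

#' Summarize a memory classification
#'
#' @param object a `memory_classification` data.frame.
#' @param ... unused.
#' @return named list of counts: per-label totals and TMG2/TMG3 by sign
#'   (TMG2 counted as the union TMG3 + TMG2-only, matching the nesting
#'   TMG3 within TMG2).
#' @export
summary.memory_classification <- function(object, ...) {
  lab <- object$label
  tmg2 <- lab %in% c("TMG3", "TMG2-only")
  list(
    n_genes = nrow(object),
    label_counts = as.list(table(factor(lab, levels = c(
      "TMG3", "TMG2-only", "robust-responsive", "transient",
      "fluctuating", "non-responsive")))),
    tmg2_up = sum(tmg2 & object$sign == "up"),
    tmg2_down = sum(tmg2 & object$sign == "down"),
    tmg3_up = sum(lab == "TMG3" & object$sign == "up"),
    tmg3_down = sum(lab == "TMG3" & object$sign == "down")
  )
}
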