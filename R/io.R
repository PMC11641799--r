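#' Read a gene x sample count matrix from TSV
#'
#' First column gene ids, remaining columns one sample each.
#'
#' @param path TSV file path.
#' @return integer matrix with gene-id rownames.
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  check_counts(m)
  m
}

#' Write a count matrix as TSV
#'
#' @param counts genes x samples matrix.
#' @param path output path.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample sheet CSV
#'
#' Columns: sample_id, group, stage, lineage, condition, replicate.
#'
#' @param path CSV file path.
#' @return data.frame.
#' @export
read_samples <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "stage", "lineage", "condition")
  if (!all(need %in% names(df))) {
    stop("sample sheet needs columns: ", paste(need, collapse = ", "))
  }
  df
}

#' Read a replicate trait table CSV
#'
#' Columns: trait, stage, lineage, condition, replicate, value.
#'
#' @param path CSV file path.
#' @return data.frame.
#' @export
read_traits <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("trait", "stage", "lineage", "condition", "value")
  if (!all(need %in% names(df))) {
    stop("trait table needs columns: ", paste(need, collapse = ", "))
  }
  if (any(!is.finite(df$value))) stop("trait values must be finite")
  df
}

#' Write a contrast result as TSV
#'
#' @param res a `contrast_result` data.frame.
#' @param path output path.
#' @export
write_contrast <- function(res, path) {
  utils::write.table(as.data.frame(res), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
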