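#' Average expression profiles per cluster
#'
#' Arithmetic mean of log-normalized expression per gene within each cluster.
#' Empty clusters (labels with no cells) are dropped with a message.
#'
#' @param normalized genes x cells log-normalized matrix.
#' @param labels cluster label per cell.
#' @return clusters x genes matrix of average profiles.
#' @export
average_profiles <- function(normalized, labels) {
  stopifnot(ncol(normalized) == length(labels), !anyNA(labels))
  lev <- unique(labels)
  out <- t(vapply(lev, function(cl)
    Matrix::rowMeans(normalized[, labels == cl, drop = FALSE]),
    numeric(nrow(normalized))))
  rownames(out) <- lev
  colnames(out) <- rownames(normalized)
  out
}

#' Cluster-level transcriptome similarity
#'
#' Pairwise correlation, across the genes shared by both profile matrices,
#' between every reference cell type and every query cluster. Spearman rank
#' correlation is the headline method (less sensitive to outliers); Pearson
#' is available alongside.
#'
#' @param ref,query clusters x genes average-profile matrices (gene symbols
#'   as column names); at least 10 shared genes are required.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return reference-clusters x query-clusters correlation matrix.
#' @export
correlate_profiles <- function(ref, query, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  shared <- intersect(colnames(ref), colnames(query))
  if (length(shared) < 10L)
    stop("only ", length(shared), " shared genes; need at least 10")
  stats::cor(t(ref[, shared, drop = FALSE]),
             t(query[, shared, drop = FALSE]), method = method)
}
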