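#' Per-sample cell filter
#'
#' First-stage QC applied to each sample independently: keep cells with a
#' gene count inside `[min_genes, max_genes]` (bounds inclusive) and a
#' mitochondrial percentage strictly below `max_mito`.
#'
#' @param qc data.frame with columns `n_genes` and `pct_mito`.
#' @param min_genes,max_genes inclusive bounds on genes detected (200, 5000).
#' @param max_mito mitochondrial percentage cutoff, exclusive (10).
#' @return logical keep-mask, one entry per row of `qc`.
#' @export
per_sample_filter <- function(qc, min_genes = 200, max_genes = 5000,
                              max_mito = 10) {
  if (nrow(qc) == 0L) return(logical(0))
  qc$n_genes >= min_genes & qc$n_genes <= max_genes & qc$pct_mito < max_mito
}

#' Merged-object cell filter
#'
#' Second-stage QC applied to all samples pooled: a cell is dropped when its
#' gene count exceeds the pooled mean + `sd_mult` SD or falls below
#' `min_genes`, when its UMI total exceeds the pooled mean + `sd_mult` SD or
#' falls below `min_umi`, or when its mitochondrial percentage exceeds
#' `max_mito`. Sample SD (n-1 denominator) throughout.
#'
#' @param qc data.frame with columns `n_genes`, `n_umi`, `pct_mito` for the
#'   pooled cells (after per-sample filtering).
#' @param min_genes,min_umi lower bounds (250, 500), exclusive drops below.
#' @param max_mito mitochondrial cutoff, drop if strictly greater (2).
#' @param sd_mult multiplier on the pooled SD (2).
#' @return logical keep-mask.
#' @export
merged_filter <- function(qc, min_genes = 250, min_umi = 500, max_mito = 2,
                          sd_mult = 2) {
  if (nrow(qc) < 2L) stop("merged_filter needs at least 2 cells (SD undefined)")
  drop <- exceeds_mean_plus_ksd(qc$n_genes, sd_mult) | qc$n_genes < min_genes |
    exceeds_mean_plus_ksd(qc$n_umi, sd_mult) | qc$n_umi < min_umi |
    qc$pct_mito > max_mito
  !drop
}

#' Per-sample doublet-score mask
#'
#' Drops cells whose doublet score exceeds the mean + `sd_mult` SD of scores
#' within the cell's own sample. A sample with a single cell (SD undefined)
#' keeps its cell.
#'
#' @param scores numeric doublet scores.
#' @param sample_ids sample id per cell.
#' @param sd_mult SD multiplier (2).
#' @return logical keep-mask.
#' @export
doublet_mask <- function(scores, sample_ids, sd_mult = 2) {
  stopifnot(length(scores) == length(sample_ids), all(is.finite(scores)))
  keep <- rep(TRUE, length(scores))
  for (s in unique(sample_ids)) {
    i <- sample_ids == s
    keep[i] <- !exceeds_mean_plus_ksd(scores[i], sd_mult)
  }
  keep
}

#' Prune embedding outliers within each cluster
#'
#' Single-pass z-score pruning on the 2-D embedding: within each cluster,
#' z-scores are computed for each dimension separately (cluster mean/SD,
#' sample SD) and cells with |z| > `z_max` in either dimension are dropped.
#' Clusters with fewer than 3 cells, or with zero variance in a dimension,
#' keep all their cells in that dimension (z undefined means no outliers).
#'
#' @param cells data.frame with columns `cluster`, `dim1`, `dim2`.
#' @param z_max outlier threshold (default 3).
#' @return logical keep-mask.
#' @export
prune_clusters <- function(cells, z_max = 3) {
  stopifnot(all(c("cluster", "dim1", "dim2") %in% colnames(cells)),
            z_max > 0, all(is.finite(cells$dim1)), all(is.finite(cells$dim2)))
  keep <- rep(TRUE, nrow(cells))
  for (cl in unique(cells$cluster)) {
    i <- which(cells$cluster == cl)
    if (length(i) < 3L) next
    for (d in c("dim1", "dim2")) {
      x <- cells[[d]][i]
      s <- stats::sd(x)
      if (is.na(s) || s == 0) next
      keep[i] <- keep[i] & abs((x - mean(x)) / s) <= z_max
    }
  }
  keep
}

#' Log-normalize a count matrix
#'
#' Per-cell library-size normalization: each count is divided by the cell's
#' total, scaled by `scale_factor`, and natural-log transformed as
#' `ln(1 + scale_factor * count / total)`.
#'
#' @param counts genes x cells matrix (sparse or dense) of non-negative counts.
#' @param scale_factor scaling constant (10,000).
#' @return matrix of the same shape and sparsity with normalized values.
#' @export
log_normalize <- function(counts, scale_factor = 1e4) {
  totals <- Matrix::colSums(counts)
  if (any(totals == 0)) stop("cells with zero total counts must be removed first")
  if (methods::is(counts, "sparseMatrix")) {
    out <- counts %*% Matrix::Diagonal(x = scale_factor / totals)
    out <- methods::as(out, "CsparseMatrix")
    out@x <- log1p(out@x)
    dimnames(out) <- dimnames(counts)
    out
  } else {
    log1p(sweep(counts, 2, totals, "/") * scale_factor)
  }
}

#' Cluster-defining gene rule
#'
#' @param min_log_diff minimum average log-scale expression difference between
#'   the cluster and the rest (natural log; 0.7). The gene-ontology input
#'   variant relaxes this to -0.7 with `max_rest_detection = 0.40`.
#' @param max_rest_detection maximum fraction of rest cells detecting the gene
#'   (0.30).
#' @param alpha_adj adjusted p-value cutoff (0.05).
#' @return a `marker_rule` list.
#' @export
marker_rule <- function(min_log_diff = 0.7, max_rest_detection = 0.30,
                        alpha_adj = 0.05) {
  stopifnot(max_rest_detection > 0, max_rest_detection <= 1, alpha_adj > 0)
  structure(list(min_log_diff = min_log_diff,
                 max_rest_detection = max_rest_detection,
                 alpha_adj = alpha_adj), class = "marker_rule")
}

#' Cluster-defining genes (one-vs-rest)
#'
#' For every cluster, each gene is tested cluster-vs-rest with a two-sided
#' Wilcoxon rank-sum test on log-normalized expression, adjusted by
#' Benjamini-Hochberg across genes within the cluster. A gene is a
#' cluster-defining marker when `p_adj < alpha_adj`, the average log-scale
#' difference (mean in cluster minus mean in rest) exceeds `min_log_diff`,
#' and the fraction of rest cells with nonzero expression is at most
#' `max_rest_detection`.
#'
#' @param normalized genes x cells log-normalized matrix.
#' @param clusters cluster label per cell.
#' @param rule a [marker_rule()].
#' @return data.frame (gene, cluster, avg_log_diff, rest_detection_fraction,
#'   p, p_adj, marker); clusters with fewer than 3 cells are skipped with a
#'   warning.
#' @export
cluster_markers <- function(normalized, clusters, rule = marker_rule()) {
  stopifnot(ncol(normalized) == length(clusters))
  if (length(unique(clusters)) < 2L) stop("need at least 2 clusters")
  out <- list()
  for (cl in unique(clusters)) {
    in_cl <- clusters == cl
    if (sum(in_cl) < 3L) {
      warning("cluster ", cl, " has fewer than 3 cells; skipped")
      next
    }
    m_in <- normalized[, in_cl, drop = FALSE]
    m_out <- normalized[, !in_cl, drop = FALSE]
    avg_diff <- Matrix::rowMeans(m_in) - Matrix::rowMeans(m_out)
    rest_det <- Matrix::rowMeans(m_out > 0)
    p <- vapply(seq_len(nrow(normalized)), function(g)
      stats::wilcox.test(as.numeric(m_in[g, ]), as.numeric(m_out[g, ]),
                         exact = FALSE)$p.value, numeric(1))
    p_adj <- stats::p.adjust(p, method = "BH")
    out[[length(out) + 1L]] <- data.frame(
      gene = rownames(normalized), cluster = cl,
      avg_log_diff = as.numeric(avg_diff),
      rest_detection_fraction = as.numeric(rest_det),
      p = p, p_adj = p_adj,
      marker = p_adj < rule$alpha_adj & avg_diff > rule$min_log_diff &
        rest_det <= rule$max_rest_detection,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Pseudobulk aggregation of raw counts
#'
#' Sums raw counts per gene over every (sample, label) combination, yielding
#' bulk-like integer profiles.
#'
#' @param counts genes x cells raw count matrix.
#' @param labels per-cell cluster/lineage label (the crudest annotation level).
#' @param sample_ids per-cell sample id.
#' @return genes x (sample.label) matrix of summed counts; column names are
#'   `sample.label`.
#' @export
pseudobulk <- function(counts, labels, sample_ids) {
  stopifnot(ncol(counts) == length(labels), ncol(counts) == length(sample_ids))
  grp <- factor(paste(sample_ids, labels, sep = "."))
  ind <- Matrix::sparseMatrix(i = seq_along(grp), j = as.integer(grp), x = 1,
                              dims = c(length(grp), nlevels(grp)))
  agg <- as.matrix(counts %*% ind)
  colnames(agg) <- levels(grp)
  agg
}

#' Run the staged QC pipeline
#'
#' Applies the filters in the prescribed order: per-sample filter, pooled
#' (merged) filter, per-sample doublet mask, then cluster pruning on the
#' embedding. Each stage sees only the survivors of the previous one; the
#' returned stage table records survivors at every stage, so drops plus
#' survivors reconcile with the input size.
#'
#' @param cells per-cell metadata with `sample_id`, `n_genes`, `n_umi`,
#'   `pct_mito`, `doublet_score`, `cluster`, `dim1`, `dim2`.
#' @param min_genes,max_genes,max_mito per-sample filter parameters.
#' @param merged_min_genes,merged_min_umi,merged_max_mito,sd_mult merged
#'   filter parameters.
#' @param prune_z cluster-pruning z threshold.
#' @return list with `keep` (logical over input cells) and `stages`
#'   (data.frame of per-stage survivor counts).
#' @export
run_qc <- function(cells, min_genes = 200, max_genes = 5000, max_mito = 10,
                   merged_min_genes = 250, merged_min_umi = 500,
                   merged_max_mito = 2, sd_mult = 2, prune_z = 3) {
  n0 <- nrow(cells)
  keep <- rep(TRUE, n0)
  for (s in unique(cells$sample_id)) {
    i <- which(cells$sample_id == s)
    keep[i] <- per_sample_filter(cells[i, ], min_genes, max_genes, max_mito)
  }
  n1 <- sum(keep)
  i <- which(keep)
  keep[i] <- merged_filter(cells[i, ], merged_min_genes, merged_min_umi,
                           merged_max_mito, sd_mult)
  n2 <- sum(keep)
  i <- which(keep)
  keep[i] <- doublet_mask(cells$doublet_score[i], cells$sample_id[i], sd_mult)
  n3 <- sum(keep)
  i <- which(keep)
  keep[i] <- prune_clusters(cells[i, ], z_max = prune_z)
  n4 <- sum(keep)
  list(keep = keep,
       stages = data.frame(
         stage = c("input", "per_sample_filter", "merged_filter",
                   "doublet_mask", "prune_clusters"),
         cells = c(n0, n1, n2, n3, n4)))
}
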