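#' Per-sample cell-type composition table
#'
#' @param cells per-cell metadata with `sample_id` and `cluster`.
#' @return data.frame (sample_id, cell_type, count, proportion); per-sample
#'   proportions sum to 1.
#' @export
composition_table <- function(cells) {
  tab <- table(cells$sample_id, cells$cluster)
  out <- as.data.frame(tab, stringsAsFactors = FALSE)
  colnames(out) <- c("sample_id", "cell_type", "count")
  totals <- stats::ave(out$count, out$sample_id, FUN = sum)
  out$proportion <- out$count / totals
  out[order(out$sample_id, out$cell_type), , drop = FALSE]
}

#' Estimate the peripheral (erythrocyte) fraction per sample
#'
#' The erythrocyte proportion of a CSF sample is taken to represent the
#' peripheral-blood contribution to that sample.
#'
#' @param cells per-cell metadata with `sample_id` and `cluster`.
#' @param ery_label cluster label identifying erythrocytes.
#' @return named numeric vector, erythrocyte fraction per sample.
#' @export
estimate_peripheral_fraction <- function(cells, ery_label = "Erythrocyte") {
  if (nrow(cells) == 0L) stop("empty cell table")
  samples <- unique(cells$sample_id)
  vapply(samples, function(s) {
    i <- cells$sample_id == s
    mean(cells$cluster[i] == ery_label)
  }, numeric(1))
}

#' Correct cell-type counts for peripheral contribution
#'
#' For cell type t in sample s with count n_t and within-sample proportion
#' p_t, the corrective factor is p_ery(s) * p_t, the corrective count is that
#' factor times n_t, and the corrected count is n_t - p_ery(s) * p_t * n_t =
#' n_t * (1 - p_ery(s) * p_t). Corrected proportions are recomputed from the
#' corrected counts. Corrected counts are kept as reals unless `round = TRUE`.
#'
#' @param table a [composition_table()].
#' @param peripheral_fraction named per-sample erythrocyte proportion, as from
#'   [estimate_peripheral_fraction()]; values must be < 1.
#' @param round emit integer corrected counts (default FALSE).
#' @return the table with `corrected_count` and `corrected_proportion` added.
#' @export
correct_counts <- function(table, peripheral_fraction, round = FALSE) {
  stopifnot(all(table$sample_id %in% names(peripheral_fraction)))
  p_ery <- peripheral_fraction[table$sample_id]
  if (any(p_ery >= 1)) stop("peripheral fraction must be < 1")
  if (any(p_ery < 0)) stop("peripheral fraction must be >= 0")
  corrective <- p_ery * table$proportion * table$count
  corrected <- table$count - corrective
  if (round) corrected <- round(corrected)
  table$corrected_count <- as.numeric(corrected)
  totals <- stats::ave(table$corrected_count, table$sample_id, FUN = sum)
  table$corrected_proportion <- ifelse(totals > 0,
                                       table$corrected_count / totals, 0)
  table
}

#' Remove erythrocytes and platelets from a cell table
#'
#' @param cells per-cell metadata with a `cluster` column.
#' @param types cluster labels to remove.
#' @return the cell table without the listed types; other rows untouched.
#' @export
remove_compartment_cells <- function(cells,
                                     types = c("Erythrocyte", "Platelet")) {
  out <- cells[!(cells$cluster %in% types), , drop = FALSE]
  rownames(out) <- NULL
  out
}
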