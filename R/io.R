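# Plain deterministic TSV writers: no quotes, no row names, fixed column order.
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a cohort in 10x triplet format
#'
#' Writes `matrix.mtx`, `features.tsv`, `barcodes.tsv`, and the per-cell
#' metadata as `cells.tsv` into `dir`.
#'
#' @param cohort a `synthetic_cohort` (or any list with `counts` and `cells`).
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort_10x <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(cohort$counts, file.path(dir, "matrix.mtx"))
  feat <- data.frame(id = rownames(cohort$counts),
                     name = rownames(cohort$counts),
                     type = "Gene Expression")
  utils::write.table(feat, file.path(dir, "features.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(colnames(cohort$counts), file.path(dir, "barcodes.tsv"))
  write_tsv(cohort$cells, file.path(dir, "cells.tsv"))
  invisible(dir)
}

#' Read a cohort from 10x triplet format
#'
#' @param dir directory holding `matrix.mtx`, `features.tsv`,
#'   `barcodes.tsv`, and optionally `cells.tsv`.
#' @return list with `counts` (sparse genes x cells) and `cells` (metadata
#'   data.frame or NULL).
#' @export
read_cohort_10x <- function(dir) {
  counts <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")),
                        "CsparseMatrix")
  feat <- utils::read.delim(file.path(dir, "features.tsv"), header = FALSE,
                            stringsAsFactors = FALSE)
  rownames(counts) <- feat[[1]]
  colnames(counts) <- readLines(file.path(dir, "barcodes.tsv"))
  cells_path <- file.path(dir, "cells.tsv")
  cells <- if (file.exists(cells_path)) read_tsv(cells_path) else NULL
  list(counts = counts, cells = cells)
}

#' Write / read TCR contigs in CellRanger dialect
#'
#' The CSV carries the `filtered_contig_annotations.csv` columns (barcode,
#' is_cell, chain, v_gene, j_gene, cdr3, cdr3_nt, reads, umis,
#' raw_clonotype_id) plus any sample annotation columns present.
#'
#' @param contigs contig data.frame.
#' @param path CSV path.
#' @return the path / the contig data.frame.
#' @export
write_contigs <- function(contigs, path) {
  utils::write.csv(contigs, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_contigs
#' @export
read_contigs <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read an NPX matrix with covariates
#'
#' The wide CSV has assays as rows (first column `assay`) and samples as
#' columns; covariates go to a companion CSV (sample_id, group, age, sex).
#'
#' @param m assays x samples matrix.
#' @param covariates covariate data.frame or NULL.
#' @param path matrix CSV path; covariates are written next to it with a
#'   `_covariates.csv` suffix.
#' @return the path / a list with `matrix` and `covariates`.
#' @export
write_npx <- function(m, covariates, path) {
  df <- data.frame(assay = rownames(m), m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(covariates))
    utils::write.csv(covariates, sub("\\.csv$", "_covariates.csv", path),
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_npx
#' @export
read_npx <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  cov_path <- sub("\\.csv$", "_covariates.csv", path)
  covariates <- if (file.exists(cov_path))
    utils::read.csv(cov_path, stringsAsFactors = FALSE) else NULL
  list(matrix = m, covariates = covariates)
}
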