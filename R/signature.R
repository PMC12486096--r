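#' The 14-gene interferon signature module
#'
#' The interferon-response gene program scored across clusters: IFNG, JAK2,
#' IFI6, IFITM2, IFITM3, IRF1, IRF7, IRF9, ISG15, MX1, MX2, OAS1, STAT1, and
#' IFNGR2.
#'
#' @return a `gene_module` (list with `name` and `genes`).
#' @export
ifn_signature <- function() {
  gene_module("IFN_signature", IFN_GENES)
}

#' Define a gene module
#'
#' @param name module name.
#' @param genes character vector of unique gene symbols.
#' @return a `gene_module`.
#' @export
gene_module <- function(name, genes) {
  stopifnot(is.character(genes), length(genes) > 0)
  if (anyDuplicated(genes)) stop("module genes must be unique")
  structure(list(name = name, genes = genes), class = "gene_module")
}

#' Binned-control average module score
#'
#' Genes are ranked by their mean expression across cells and cut into
#' `n_bins` near-equal-size bins; for each module gene, up to `n_ctrl`
#' control genes are sampled (seeded, without replacement) from the
#' non-module genes of the gene's bin. The per-cell score is the mean
#' log-normalized expression of the module genes minus the mean over the
#' pooled control genes, so a module drawn at random from an exchangeable
#' matrix scores about zero. Module genes are excluded from the control
#' pool because on matrices of a few hundred genes a coherent module can
#' fill most of its own bin and cancel itself; if a bin holds no other
#' genes the full bin is used with a warning.
#'
#' @param normalized genes x cells log-normalized matrix with row names.
#' @param module a [gene_module()]; module genes missing from the matrix are
#'   dropped with a warning, and an error is raised if none remain.
#' @param n_bins expression bins (24).
#' @param n_ctrl control genes sampled per module gene (100).
#' @param seed integer seed for control sampling.
#' @return named numeric vector of per-cell scores.
#' @export
module_score <- function(normalized, module, n_bins = 24L, n_ctrl = 100L,
                         seed = 1L) {
  stopifnot(inherits(module, "gene_module"),
            !is.null(rownames(normalized)))
  if (nrow(normalized) < n_bins)
    stop("need at least n_bins = ", n_bins, " genes")
  present <- intersect(module$genes, rownames(normalized))
  missing <- setdiff(module$genes, present)
  if (length(missing))
    warning("module genes absent from matrix, dropped: ",
            paste(missing, collapse = ", "))
  if (!length(present)) stop("module entirely absent from matrix")

  avg <- Matrix::rowMeans(normalized)
  rk <- rank(avg, ties.method = "first")
  bin <- ceiling(n_bins * rk / length(rk))
  names(bin) <- rownames(normalized)

  in_module <- rownames(normalized) %in% present
  ctrl_idx <- with_seed(child_seed(seed, "module_score"), {
    unlist(lapply(present, function(g) {
      pool <- which(bin == bin[[g]] & !in_module)
      if (!length(pool)) {
        warning("bin of ", g, " holds no non-module genes; using full bin")
        pool <- which(bin == bin[[g]])
      }
      sample(pool, min(n_ctrl, length(pool)))
    }))
  })
  mod_score <- Matrix::colMeans(normalized[present, , drop = FALSE])
  ctrl_score <- Matrix::colMeans(normalized[ctrl_idx, , drop = FALSE])
  as.numeric(mod_score - ctrl_score) |>
    stats::setNames(colnames(normalized))
}

#' Summarize module scores by group
#'
#' Per-group descriptive statistics plus a Kruskal-Wallis omnibus rank test
#' across groups (descriptives only when a single group is supplied).
#'
#' @param scores per-cell scores from [module_score()].
#' @param groups group label per cell.
#' @return list with `summary` (group, n, mean, median) and `p` (omnibus
#'   Kruskal-Wallis p-value, or NA for a single group; 1 when all scores are
#'   tied).
#' @export
score_by_group <- function(scores, groups) {
  stopifnot(length(scores) == length(groups))
  lev <- unique(groups)
  summary <- data.frame(
    group = lev,
    n = vapply(lev, function(g) sum(groups == g), integer(1)),
    mean = vapply(lev, function(g) mean(scores[groups == g]), numeric(1)),
    median = vapply(lev, function(g) stats::median(scores[groups == g]),
                    numeric(1)),
    stringsAsFactors = FALSE)
  p <- NA_real_
  if (length(lev) >= 2L) {
    p <- if (length(unique(scores)) == 1L) 1 else
      stats::kruskal.test(scores, factor(groups))$p.value
  }
  list(summary = summary, p = p)
}
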