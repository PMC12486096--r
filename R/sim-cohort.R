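# Structured gene universe shared by the generator: the 14 interferon-module
# genes, a high-expression housekeeping block (the controls the module score
# draws from), mitochondrial genes, per-type marker blocks, disjoint
# erythrocyte/platelet marker blocks, and unstructured filler.

IFN_GENES <- c("IFNG", "JAK2", "IFI6", "IFITM2", "IFITM3", "IRF1", "IRF7",
               "IRF9", "ISG15", "MX1", "MX2", "OAS1", "STAT1", "IFNGR2")
MT_GENES <- c("MT-CO1", "MT-ND1", "MT-CYB", "MT-ATP6", "MT-ND4")
ERY_GENES <- c("HBB", "HBA1", "HBA2", "HBD", "ALAS2", "SLC4A1")
PLT_GENES <- c("PPBP", "PF4", "TUBB1", "ITGA2B")

gene_universe <- function(config) {
  types <- names(config$cell_types)
  markers <- unlist(lapply(types, function(t) paste0(t, "_M", 1:6)))
  n_hk <- 40L
  structured <- c(IFN_GENES, MT_GENES, paste0("HK", sprintf("%03d", 1:n_hk)),
                  markers, ERY_GENES, PLT_GENES)
  n_fill <- config$n_genes - length(structured)
  if (n_fill < 0)
    stop("n_genes too small: need at least ", length(structured), " genes")
  genes <- c(structured, if (n_fill > 0) paste0("G", sprintf("%04d", seq_len(n_fill))))
  class <- rep("filler", length(genes))
  class[seq_along(IFN_GENES)] <- "ifn"
  class[genes %in% MT_GENES] <- "mito"
  class[startsWith(genes, "HK")] <- "housekeeping"
  class[genes %in% markers] <- "marker"
  class[genes %in% ERY_GENES] <- "ery"
  class[genes %in% PLT_GENES] <- "platelet"
  marker_type <- rep(NA_character_, length(genes))
  for (t in types) marker_type[genes %in% paste0(t, "_M", 1:6)] <- t
  data.frame(gene = genes, class = class, marker_type = marker_type,
             stringsAsFactors = FALSE)
}

# Expected mean-count vector for a cell of `type` in `group`.
type_group_means <- function(config, universe, type, group) {
  mu <- rep(config$baseline_mean, nrow(universe))
  mu[universe$class == "housekeeping"] <- config$hk_mean
  mu[universe$class == "mito"] <- 1
  mu[universe$class %in% c("ery", "platelet")] <- 0.01
  mu[universe$class == "marker"] <- 0.02
  own <- !is.na(universe$marker_type) & universe$marker_type == type
  mu[own] <- config$baseline_mean * config$marker_fold
  mu[universe$class == "ifn"] <-
    config$hk_mean * exp(config$ifn_effect[[group]])
  mu
}

subject_table <- function(config) {
  with_seed(child_seed(config$seed, "subjects"), {
    out <- do.call(rbind, lapply(config$groups, function(g) {
      n <- config$n_samples_per_group
      data.frame(subject = sprintf("%s_S%d", g, seq_len(n)), group = g,
                 age = round(stats::runif(n, 25, 60), 1),
                 sex = sample(c("F", "M"), n, replace = TRUE),
                 stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
  })
}

#' Simulate a synthetic CSF/PBMC cohort with known ground truth
#'
#' Draws, for every subject, one CSF and one PBMC sample: cell-type counts are
#' multinomial over group-adjusted mixture proportions (baseline proportions
#' shifted by the configured per-group log2 fold-differences, renormalized),
#' and gene counts are negative binomial with type-specific marker blocks and
#' a multiplicative per-group shift on the 14 interferon-module genes.
#' Per-cell QC metrics (genes detected, total UMI, mitochondrial percentage),
#' a cluster-shaped 2-D embedding, and doublet scores are derived so the QC
#' stage can run on the output unchanged. Deterministic at fixed seed.
#'
#' @param config a [sim_config()].
#' @return an object of class `synthetic_cohort`: list with `counts` (sparse
#'   genes x cells), `cells` (per-cell metadata data.frame), `genes` (gene
#'   annotation), `config`, and `truth` (planted parameters).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  universe <- gene_universe(config)
  subjects <- subject_table(config)
  types <- names(config$cell_types)

  # group-adjusted mixture proportions
  props <- lapply(config$groups, function(g) {
    p <- config$cell_types * 2^config$composition_effects[g, ]
    p / sum(p)
  })
  names(props) <- config$groups

  mu_cache <- list()
  for (g in config$groups) for (t in types)
    mu_cache[[paste(g, t)]] <- type_group_means(config, universe, t, g)

  centers <- cbind(10 * cos(2 * pi * seq_along(types) / length(types)),
                   10 * sin(2 * pi * seq_along(types) / length(types)))
  rownames(centers) <- types

  with_seed(child_seed(config$seed, "cohort"), {
    blocks <- list(); meta <- list(); k <- 0L
    for (i in seq_len(nrow(subjects))) {
      for (comp in c("CSF", "PBMC")) {
        sub <- subjects$subject[i]; g <- subjects$group[i]
        sample_id <- paste0(sub, "_", comp)
        n <- config$n_cells_per_sample
        tc <- stats::rmultinom(1, n, props[[g]])[, 1]
        for (t in types) {
          if (tc[[t]] == 0) next
          k <- k + 1L
          mu <- mu_cache[[paste(g, t)]]
          blocks[[k]] <- matrix(
            stats::rnbinom(length(mu) * tc[[t]], mu = mu,
                           size = config$dispersion),
            nrow = length(mu))
          meta[[k]] <- data.frame(
            sample_id = sample_id, subject = sub, compartment = comp,
            group = g, cluster = t,
            dim1 = stats::rnorm(tc[[t]], centers[t, 1], 1),
            dim2 = stats::rnorm(tc[[t]], centers[t, 2], 1),
            doublet_score = stats::rgamma(tc[[t]], shape = 2, scale = 0.05),
            stringsAsFactors = FALSE)
        }
      }
    }
    counts <- do.call(cbind, blocks)
    cells <- do.call(rbind, meta)
    cells$cell_id <- paste0(cells$sample_id, "-",
                            stats::ave(seq_len(nrow(cells)), cells$sample_id,
                                       FUN = seq_along))
    rownames(counts) <- universe$gene
    colnames(counts) <- cells$cell_id
    counts <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")

    cells$n_umi <- Matrix::colSums(counts)
    cells$n_genes <- Matrix::colSums(counts > 0)
    cells$pct_mito <- 100 * Matrix::colSums(counts[MT_GENES, , drop = FALSE]) /
      pmax(cells$n_umi, 1)
    cells <- cells[, c("cell_id", "sample_id", "subject", "compartment",
                       "group", "cluster", "dim1", "dim2", "doublet_score",
                       "n_genes", "n_umi", "pct_mito")]
    rownames(cells) <- NULL

    samples <- unique(cells$sample_id)
    truth <- list(
      composition_effects = config$composition_effects,
      ifn_effect = config$ifn_effect,
      contamination_fraction = stats::setNames(rep(0, length(samples)), samples),
      subjects = subjects)
    structure(list(counts = counts, cells = cells, genes = universe,
                   config = config, truth = truth),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("synthetic_cohort:", nrow(x$counts), "genes x", ncol(x$counts), "cells;",
      length(unique(x$cells$sample_id)), "samples,",
      length(unique(x$cells$group)), "groups\n")
  invisible(x)
}

#' Spike erythrocyte and platelet contamination into a cohort
#'
#' Appends erythrocyte-labeled (and, optionally, platelet-labeled) cells to
#' each sample so that erythrocytes make up the requested fraction of the
#' sample's cells after spiking; pre-existing cells are untouched. The
#' erythrocyte count solves n_ery / (N + n_ery + n_plt) = fraction with
#' n_plt = platelet_ratio * n_ery, so [estimate_peripheral_fraction()]
#' round-trips the request to within integer rounding.
#'
#' @param cohort a `synthetic_cohort`.
#' @param fractions per-sample erythrocyte fraction in [0, 1); a scalar is
#'   recycled, or a named vector keyed by sample id.
#' @param platelet_ratio platelets appended per erythrocyte (default 0.5).
#' @return the cohort with contaminant cells appended and
#'   `truth$contamination_fraction` updated to the realized fractions.
#' @export
spike_contamination <- function(cohort, fractions, platelet_ratio = 0.5) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  samples <- unique(cohort$cells$sample_id)
  if (length(fractions) == 1L && is.null(names(fractions)))
    fractions <- stats::setNames(rep(fractions, length(samples)), samples)
  stopifnot(all(samples %in% names(fractions)))
  if (any(fractions < 0)) stop("contamination fraction must be >= 0")
  if (any(fractions * (1 + platelet_ratio) >= 1))
    stop("contamination fraction too large: fraction * (1 + platelet_ratio) must be < 1")

  universe <- cohort$genes
  # contaminant cells share the baseline library profile (so they survive the
  # generic QC floors, as real droplets do) plus a disjoint marker block that
  # makes annotation unambiguous
  mu_contam <- function(kind) {
    mu <- rep(cohort$config$baseline_mean, nrow(universe))
    mu[universe$class == "housekeeping"] <- cohort$config$hk_mean
    mu[universe$class == "mito"] <- 0.5
    mu[universe$class == if (kind == "Erythrocyte") "ery" else "platelet"] <-
      if (kind == "Erythrocyte") 20 else 15
    mu
  }

  with_seed(child_seed(cohort$config$seed, "contamination"), {
    add_counts <- list(); add_meta <- list(); k <- 0L
    for (s in samples) {
      f <- fractions[[s]]
      if (f == 0) next
      N <- sum(cohort$cells$sample_id == s)
      n_ery <- round(f * N / (1 - f * (1 + platelet_ratio)))
      n_plt <- round(platelet_ratio * n_ery)
      info <- cohort$cells[match(s, cohort$cells$sample_id), ]
      for (kind in c("Erythrocyte", "Platelet")) {
        n <- if (kind == "Erythrocyte") n_ery else n_plt
        if (n == 0) next
        k <- k + 1L
        mu <- mu_contam(kind)
        add_counts[[k]] <- matrix(
          stats::rnbinom(length(mu) * n, mu = mu,
                         size = cohort$config$dispersion),
          nrow = length(mu))
        add_meta[[k]] <- data.frame(
          cell_id = sprintf("%s-%s%d", s, tolower(substr(kind, 1, 3)), seq_len(n)),
          sample_id = s, subject = info$subject, compartment = info$compartment,
          group = info$group, cluster = kind,
          dim1 = stats::rnorm(n, if (kind == "Erythrocyte") 20 else -20, 1),
          dim2 = stats::rnorm(n, 20, 1),
          doublet_score = stats::rgamma(n, shape = 2, scale = 0.05),
          stringsAsFactors = FALSE)
      }
    }
    if (k == 0L) {
      cohort$truth$contamination_fraction[names(fractions)] <- fractions
      return(cohort)
    }
    newm <- do.call(cbind, add_counts)
    newmeta <- do.call(rbind, add_meta)
    rownames(newm) <- universe$gene
    colnames(newm) <- newmeta$cell_id
    newmeta$n_umi <- colSums(newm)
    newmeta$n_genes <- colSums(newm > 0)
    newmeta$pct_mito <- 100 * colSums(newm[MT_GENES, , drop = FALSE]) /
      pmax(newmeta$n_umi, 1)
    newm <- methods::as(Matrix::Matrix(newm, sparse = TRUE), "CsparseMatrix")

    cohort$counts <- cbind(cohort$counts, newm)
    cohort$cells <- rbind(cohort$cells,
                          newmeta[, colnames(cohort$cells), drop = FALSE])
    ord <- order(match(cohort$cells$sample_id, samples))
    cohort$cells <- cohort$cells[ord, ]
    rownames(cohort$cells) <- NULL
    cohort$counts <- cohort$counts[, cohort$cells$cell_id]
    cohort$truth$contamination_fraction[names(fractions)] <- fractions
    cohort
  })
}
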