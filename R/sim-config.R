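#' Configuration for the synthetic cohort generator
#'
#' Bundles every parameter of the synthetic cohort: the group design (PRL
#' categories), cell-type mixture and per-group composition shifts, the
#' negative-binomial expression model with a planted interferon-module shift,
#' blood-contamination fractions, the TCR repertoire model, and the Olink-style
#' NPX model with age/sex covariates and a low-abundance noise floor.
#'
#' Defaults encode a desk-scale cohort with the structure the downstream
#' analyses assume: three PRL categories (none / low / high), paired CSF and
#' PBMC samples per subject, a graded interferon-signature shift, a 2-fold
#' planted enrichment of B-memory cells in PRL-high, and NPX assays spanning
#' three orders of magnitude of abundance so the CV noise floor is visible.
#'
#' @param groups character vector of group labels, ordered by PRL burden.
#' @param n_samples_per_group subjects per group; each subject contributes one
#'   CSF and one PBMC sample.
#' @param cell_types named numeric vector of baseline mixture proportions
#'   (must sum to 1).
#' @param composition_effects numeric matrix (groups x cell types) of log2
#'   fold-differences applied to the baseline proportions before
#'   renormalization. Default plants log2FD = 1 for B-memory and Treg in the
#'   PRL-high group.
#' @param n_cells_per_sample cells drawn per sample.
#' @param n_genes total genes in the matrix (>= the built-in structured genes).
#' @param baseline_mean mean counts per cell for unstructured filler genes.
#' @param marker_fold fold elevation of a cell type's marker genes in that type.
#' @param hk_mean mean counts for the high-expression housekeeping block (also
#'   the baseline of the 14 interferon-module genes, so their log-normalized
#'   values sit well above the count floor).
#' @param dispersion negative-binomial size parameter shared across genes.
#' @param ifn_effect named per-group natural-log fold shift applied
#'   multiplicatively to the interferon-module genes.
#' @param contamination_fraction per-sample erythrocyte fraction in [0, 1)
#'   used by [spike_contamination()]; scalar is recycled.
#' @param tcr list: `exponent` (power-law exponent > 1), `n_clones` per
#'   repertoire, `sharing` (probability a blood clone is shared with the same
#'   subject's CSF), `cdr3_length` (nt, multiple of 3).
#' @param npx list: `n_assays`, `beta_age` (log2 NPX per year), `beta_sex`
#'   (log2 NPX, male vs female), `group_effects` (named per-group log2 shift),
#'   `group_assay_ids` (assay indices carrying the group effect in both
#'   compartments), `csf_only_assay_ids` (assay indices carrying it in CSF
#'   only), `cv_floor` c(a, b) with CV(mu) = a + b/sqrt(mu) on the linear
#'   scale, `baseline_range` log2 span of assay abundances.
#' @param seed integer global seed; all sub-generators derive child seeds from
#'   it via [child_seed()].
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(groups = c("noPRL", "PRLlow", "PRLhigh"),
                       n_samples_per_group = 3L,
                       cell_types = c(CD4_TCM = 0.22, CD4_TEM = 0.10,
                                      CD8_TEM = 0.15, Treg = 0.05,
                                      B_memory = 0.08, NK = 0.10,
                                      Mono = 0.25, pDC = 0.05),
                       composition_effects = NULL,
                       n_cells_per_sample = 600L,
                       n_genes = 600L,
                       baseline_mean = 1,
                       marker_fold = 8,
                       hk_mean = 20,
                       dispersion = 2,
                       ifn_effect = NULL,
                       contamination_fraction = 0,
                       tcr = list(),
                       npx = list(),
                       seed = 1L) {
  if (abs(sum(cell_types) - 1) > 1e-12)
    stop("cell_types baseline proportions must sum to 1")
  if (any(cell_types <= 0)) stop("cell_types proportions must be positive")
  if (is.null(composition_effects)) {
    composition_effects <- matrix(0, length(groups), length(cell_types),
                                  dimnames = list(groups, names(cell_types)))
    if (all(c("PRLhigh", "B_memory") %in% c(groups, names(cell_types)))) {
      composition_effects["PRLhigh", "B_memory"] <- 1
      composition_effects["PRLhigh", "Treg"] <- 1
    }
  }
  stopifnot(identical(rownames(composition_effects), groups),
            identical(colnames(composition_effects), names(cell_types)))
  if (is.null(ifn_effect)) {
    ifn_effect <- stats::setNames(seq(0, 0.8, length.out = length(groups)),
                                  groups)
  }
  stopifnot(identical(names(ifn_effect), groups))
  if (any(contamination_fraction < 0 | contamination_fraction >= 1))
    stop("contamination_fraction must be in [0, 1)")
  if (baseline_mean <= 0 || hk_mean <= 0 || dispersion <= 0 || marker_fold <= 0)
    stop("count model parameters must be positive")

  tcr <- utils::modifyList(list(exponent = 2.0, n_clones = 100L,
                                sharing = 0.3, cdr3_length = 45L,
                                t_cell_types = c("CD4_TCM", "CD4_TEM",
                                                 "CD8_TEM", "Treg")), tcr)
  if (tcr$exponent <= 1) stop("tcr$exponent must be > 1")
  if (tcr$sharing < 0 || tcr$sharing > 1) stop("tcr$sharing must be in [0,1]")
  if (tcr$cdr3_length %% 3 != 0) stop("tcr$cdr3_length must be a multiple of 3")

  npx <- utils::modifyList(list(
    n_assays = 60L, beta_age = 0.02, beta_sex = 0.5,
    group_effects = stats::setNames(seq(0, 1, length.out = length(groups)),
                                    groups),
    group_assay_ids = 40:47, csf_only_assay_ids = 48:51,
    cv_floor = c(a = 0.1, b = 0.5), baseline_range = c(1, 10)), npx)
  stopifnot(identical(names(npx$group_effects), groups),
            npx$cv_floor[["a"]] >= 0, npx$cv_floor[["b"]] >= 0)
  if (length(intersect(npx$group_assay_ids, npx$csf_only_assay_ids)))
    stop("group_assay_ids and csf_only_assay_ids must be disjoint")

  cfg <- list(groups = groups,
              n_samples_per_group = as.integer(n_samples_per_group),
              cell_types = cell_types,
              composition_effects = composition_effects,
              n_cells_per_sample = as.integer(n_cells_per_sample),
              n_genes = as.integer(n_genes),
              baseline_mean = baseline_mean, marker_fold = marker_fold,
              hk_mean = hk_mean, dispersion = dispersion,
              ifn_effect = ifn_effect,
              contamination_fraction = contamination_fraction,
              tcr = tcr, npx = npx, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  gene_universe(cfg)  # validates n_genes against the structured gene blocks
  cfg
}

#' Read or write a simulation configuration as YAML
#'
#' @param path file path.
#' @param config a `sim_config` object (for writing).
#' @return `read_sim_config` returns a validated `sim_config`.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$cell_types)) raw$cell_types <- unlist(raw$cell_types)
  if (!is.null(raw$ifn_effect)) raw$ifn_effect <- unlist(raw$ifn_effect)
  if (!is.null(raw$composition_effects)) {
    ce <- raw$composition_effects
    m <- do.call(rbind, lapply(ce, unlist))
    raw$composition_effects <- m
  }
  if (!is.null(raw$npx$group_effects))
    raw$npx$group_effects <- unlist(raw$npx$group_effects)
  if (!is.null(raw$npx$cv_floor)) raw$npx$cv_floor <- unlist(raw$npx$cv_floor)
  do.call(sim_config, raw)
}

#' @rdname read_sim_config
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  out <- unclass(config)
  # yaml drops names of atomic vectors; write named vectors as maps
  out$cell_types <- as.list(config$cell_types)
  out$ifn_effect <- as.list(config$ifn_effect)
  out$composition_effects <- apply(config$composition_effects, 1, as.list,
                                   simplify = FALSE)
  out$npx$group_effects <- as.list(config$npx$group_effects)
  out$npx$cv_floor <- as.list(config$npx$cv_floor)
  yaml::write_yaml(out, path)
  invisible(path)
}
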