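#' Categorize a paramagnetic rim lesion count
#'
#' Case stratification by PRL burden: 0 lesions is "none", 1-3 "low",
#' 4 or more "high".
#'
#' @param prl_count non-negative integer vector of PRL counts.
#' @return character vector of categories.
#' @export
categorize_prl <- function(prl_count) {
  if (any(prl_count < 0)) stop("PRL counts must be non-negative")
  ifelse(prl_count == 0, "none", ifelse(prl_count <= 3, "low", "high"))
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes the stages in order — simulate, qc, contam, composition, score,
#' tcr, olink, similarity — for one group comparison, writing per-stage TSV
#' outputs, a machine-readable JSON manifest (parameters, seed, per-stage
#' record counts), and a plain-text log into `out_dir`. CSF and PBMC are
#' processed as separate objects throughout. Re-running with the same config
#' reproduces byte-identical outputs. Disabling a stage makes any later stage
#' that consumes it fail fast with a named dependency error.
#'
#' @param config a [sim_config()].
#' @param out_dir run directory (created; must not contain a prior manifest
#'   unless `overwrite = TRUE`).
#' @param cond_a,cond_b groups compared by the composition, scoring, and
#'   proteomics stages; default the first and last configured group.
#' @param stages character vector of stages to run (default all).
#' @param contamination per-sample erythrocyte spike fraction handed to
#'   [spike_contamination()]; default the config's `contamination_fraction`.
#' @param overwrite allow writing into an existing run directory.
#' @return invisibly, a list with the run directory, the manifest, and the
#'   in-memory stage results.
#' @export
run_pipeline <- function(config = sim_config(), out_dir,
                         cond_a = config$groups[1],
                         cond_b = config$groups[length(config$groups)],
                         stages = c("simulate", "qc", "contam", "composition",
                                    "score", "tcr", "olink", "similarity"),
                         contamination = config$contamination_fraction,
                         overwrite = FALSE) {
  all_stages <- c("simulate", "qc", "contam", "composition", "score", "tcr",
                  "olink", "similarity")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  deps <- list(qc = "simulate", contam = "qc", composition = "contam",
               score = "contam", tcr = "simulate", olink = "simulate",
               similarity = "contam")
  for (s in stages) {
    missing_dep <- setdiff(deps[[s]], stages)
    if (length(missing_dep))
      stop("stage '", s, "' requires disabled stage '", missing_dep[1], "'")
  }
  if (!overwrite && file.exists(file.path(out_dir, "manifest.json")))
    stop("run directory already holds a manifest; use overwrite = TRUE")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  note <- function(...) log_lines <<- c(log_lines, paste0(...))
  counts_of <- list()
  res <- list()
  run_stage <- function(name, fun) {
    tryCatch(fun(), error = function(e) {
      writeLines(log_lines, file.path(out_dir, "log.txt"))
      stop("stage '", name, "' failed after ",
           paste(names(counts_of), unlist(counts_of), sep = "=",
                 collapse = ", "), ": ", conditionMessage(e), call. = FALSE)
    })
  }

  if ("simulate" %in% stages) run_stage("simulate", function() {
    cohort <- simulate_cohort(config)
    if (any(contamination > 0))
      cohort <- spike_contamination(cohort, contamination)
    res$cohort <<- cohort
    counts_of$simulate <<- nrow(cohort$cells)
    note("simulate: ", nrow(cohort$cells), " cells, ",
         nrow(cohort$counts), " genes")
  })

  if ("qc" %in% stages) run_stage("qc", function() {
    qc <- run_qc(res$cohort$cells)
    write_tsv(qc$stages, file.path(out_dir, "qc_stages.tsv"))
    res$cohort$cells <<- res$cohort$cells[qc$keep, ]
    res$cohort$counts <<- res$cohort$counts[, qc$keep]
    counts_of$qc <<- sum(qc$keep)
    note("qc: ", sum(qc$keep), " cells survive")
  })

  if ("contam" %in% stages) run_stage("contam", function() {
    cells <- res$cohort$cells
    comp <- composition_table(cells)
    p_ery <- estimate_peripheral_fraction(cells)
    corrected <- correct_counts(comp, p_ery)
    write_tsv(corrected, file.path(out_dir, "composition_corrected.tsv"))
    keep <- !(cells$cluster %in% c("Erythrocyte", "Platelet"))
    res$cohort$cells <<- cells[keep, ]
    res$cohort$counts <<- res$cohort$counts[, keep]
    counts_of$contam <<- sum(keep)
    note("contam: erythrocyte fractions ",
         paste(sprintf("%.3f", p_ery), collapse = " "))
  })

  for (comp_name in c("CSF", "PBMC")) {
    local({
      cn <- comp_name
      if ("composition" %in% stages) run_stage("composition", function() {
        cells <- res$cohort$cells[res$cohort$cells$compartment == cn, ]
        pt <- proportion_test(cells, cond_a, cond_b, seed = config$seed)
        write_tsv(pt, file.path(out_dir,
                                paste0("composition_", tolower(cn), ".tsv")))
        res[[paste0("composition_", cn)]] <<- pt
        counts_of[[paste0("composition_", cn)]] <<- nrow(cells)
        note("composition ", cn, ": ", sum(pt$significant),
             " significant clusters")
      })
      if ("score" %in% stages) run_stage("score", function() {
        i <- res$cohort$cells$compartment == cn
        norm <- log_normalize(res$cohort$counts[, i])
        sc <- module_score(norm, ifn_signature(), seed = config$seed)
        sg <- score_by_group(sc, res$cohort$cells$group[i])
        out <- data.frame(cell_id = res$cohort$cells$cell_id[i],
                          group = res$cohort$cells$group[i],
                          cluster = res$cohort$cells$cluster[i],
                          ifn_score = as.numeric(sc))
        write_tsv(out, file.path(out_dir, paste0("ifn_scores_",
                                                 tolower(cn), ".tsv")))
        write_tsv(sg$summary, file.path(out_dir, paste0("ifn_score_summary_",
                                                        tolower(cn), ".tsv")))
        res[[paste0("scores_", cn)]] <<- sc
        counts_of[[paste0("score_", cn)]] <<- length(sc)
        note("score ", cn, ": Kruskal-Wallis p = ", format(sg$p, digits = 3))
      })
    })
  }

  if ("tcr" %in% stages) run_stage("tcr", function() {
    sim <- simulate_tcr(res$cohort)
    write_contigs(sim$contigs, file.path(out_dir, "contigs.csv"))
    for (cn in c("CSF", "PBMC")) {
      calls <- call_clones(sim$contigs[sim$contigs$compartment == cn, ])
      occ <- clonal_occupancy(calls)
      calls$cells$clonality <- stratify_clonality(calls)
      write_tsv(calls$clones, file.path(out_dir,
                                        paste0("clones_", tolower(cn), ".tsv")))
      write_tsv(occ, file.path(out_dir,
                               paste0("occupancy_", tolower(cn), ".tsv")))
      res[[paste0("clones_", cn)]] <<- calls
    }
    shared <- trace_clones(res$clones_CSF, res$clones_PBMC)
    write_tsv(shared, file.path(out_dir, "shared_clones.tsv"))
    counts_of$tcr <<- nrow(sim$contigs)
    note("tcr: ", nrow(shared), " cross-compartment clones")
  })

  if ("olink" %in% stages) run_stage("olink", function() {
    npx <- simulate_npx(config)
    norm_csf <- cyclic_loess_normalize(npx$csf)
    norm_serum <- cyclic_loess_normalize(npx$serum)
    nf_csf <- noise_filter(norm_csf)
    nf_serum <- noise_filter(norm_serum)
    da <- ancova_differential(nf_csf$retained, npx$covariates,
                              contrast = c(cond_a, cond_b))
    write_tsv(da$results, file.path(out_dir, "olink_csf.tsv"))
    ratio <- csf_serum_ratio(
      norm_csf[intersect(rownames(nf_csf$retained),
                         rownames(nf_serum$retained)), , drop = FALSE],
      norm_serum[intersect(rownames(nf_csf$retained),
                           rownames(nf_serum$retained)), , drop = FALSE])
    da_ratio <- ancova_differential(ratio, npx$covariates,
                                    contrast = c(cond_a, cond_b),
                                    fold_threshold = log2(1.25))
    write_tsv(da_ratio$results, file.path(out_dir, "olink_ratio.tsv"))
    res$olink <<- list(csf = da, ratio = da_ratio,
                       cutoffs = c(csf = nf_csf$cutoff,
                                   serum = nf_serum$cutoff))
    counts_of$olink <<- nrow(da$results)
    note("olink: ", sum(da$results$significant), " CSF hits, ",
         sum(da_ratio$results$significant), " ratio hits")
  })

  if ("similarity" %in% stages) run_stage("similarity", function() {
    profs <- lapply(c("CSF", "PBMC"), function(cn) {
      i <- res$cohort$cells$compartment == cn
      average_profiles(log_normalize(res$cohort$counts[, i]),
                       res$cohort$cells$cluster[i])
    })
    sim <- correlate_profiles(profs[[1]], profs[[2]], method = "spearman")
    write_tsv(data.frame(cluster = rownames(sim), sim, check.names = FALSE),
              file.path(out_dir, "similarity_spearman.tsv"))
    res$similarity <<- sim
    counts_of$similarity <<- length(sim)
    note("similarity: mean diagonal ",
         format(mean(diag(sim[rownames(sim),
                              intersect(colnames(sim), rownames(sim))])),
                digits = 3))
  })

  manifest <- list(package = "rimflow",
                   seed = config$seed,
                   comparison = c(cond_a, cond_b),
                   stages = stages,
                   parameters = list(
                     groups = config$groups,
                     n_samples_per_group = config$n_samples_per_group,
                     n_cells_per_sample = config$n_cells_per_sample,
                     n_genes = config$n_genes),
                   record_counts = counts_of)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(log_lines, file.path(out_dir, "log.txt"))
  invisible(list(dir = out_dir, manifest = manifest, results = res))
}
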