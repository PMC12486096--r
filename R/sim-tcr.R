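# CDR3 nucleotide sequences are random codon strings over the 61 sense codons
# (so translation never hits a stop), re-drawn on collision.
sense_codons <- function() names(GENETIC_CODE_TABLE)[GENETIC_CODE_TABLE != "*"]

gen_cdr3 <- function(n, len, used = character(0)) {
  codons <- sense_codons()
  out <- character(0)
  while (length(out) < n) {
    need <- n - length(out)
    cand <- vapply(seq_len(need), function(i)
      paste(sample(codons, len %/% 3, replace = TRUE), collapse = ""),
      character(1))
    cand <- setdiff(unique(cand), c(used, out))
    out <- c(out, cand)
  }
  out[seq_len(n)]
}

# Heavy-tailed clone sizes: n_clones raw draws from a truncated discrete power
# law P(k) ~ k^-alpha; every clone keeps one cell and the remaining cells are
# allocated multinomially with weights proportional to the raw draws, so
# n_clones = n_cells degenerates to all singletons.
draw_clone_sizes <- function(n_cells, n_clones, alpha, kmax = 1000L) {
  if (n_clones > n_cells) stop("more clones than T cells")
  k <- seq_len(kmax)
  raw <- sample(k, n_clones, replace = TRUE, prob = k^(-alpha))
  extra <- n_cells - n_clones
  if (extra == 0L) return(rep(1L, n_clones))
  add <- stats::rmultinom(1, extra, prob = raw / sum(raw))[, 1]
  as.integer(1L + add)
}

#' Simulate paired-chain TCR repertoires for a cohort's T cells
#'
#' For every subject and compartment, T cells are partitioned into clones with
#' power-law sizes; each clone carries a unique (TRA, TRB) CDR3 nucleotide
#' pair, translated to amino acids by the standard genetic code. With the
#' configured sharing probability, a blood (PBMC) clone reuses the CDR3 pair
#' of one of the same subject's CSF clones, planting cross-compartment clones
#' that [trace_clones()] must find.
#'
#' @param cohort a `synthetic_cohort`.
#' @param config a [sim_config()]; defaults to the cohort's own.
#' @return list with `contigs` (CellRanger `filtered_contig_annotations.csv`
#'   dialect: two rows per cell plus sample annotation columns) and `truth`
#'   (per-clone table with planted sharing flags).
#' @export
simulate_tcr <- function(cohort, config = cohort$config) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  tc <- config$tcr
  tcells <- cohort$cells[cohort$cells$cluster %in% tc$t_cell_types, ]
  if (nrow(tcells) == 0L) stop("cohort contains no T-lymphoid cells")

  with_seed(child_seed(config$seed, "tcr"), {
    used_tra <- character(0); used_trb <- character(0)
    contigs <- list(); truth <- list(); k <- 0L
    for (sub in unique(tcells$subject)) {
      csf_keys <- NULL
      for (comp in c("CSF", "PBMC")) {
        rep_cells <- tcells[tcells$subject == sub & tcells$compartment == comp, ]
        nT <- nrow(rep_cells)
        if (nT == 0L) next
        n_clones <- tc$n_clones
        sizes <- draw_clone_sizes(nT, n_clones, tc$exponent)
        tra <- gen_cdr3(n_clones, tc$cdr3_length, used_tra)
        trb <- gen_cdr3(n_clones, tc$cdr3_length, used_trb)
        used_tra <- c(used_tra, tra); used_trb <- c(used_trb, trb)
        shared <- rep(FALSE, n_clones)
        if (comp == "PBMC" && !is.null(csf_keys) && tc$sharing > 0) {
          reuse <- which(stats::runif(n_clones) < tc$sharing)
          reuse <- reuse[seq_len(min(length(reuse), nrow(csf_keys)))]
          if (length(reuse)) {
            src <- sample(nrow(csf_keys), length(reuse))
            tra[reuse] <- csf_keys$tra[src]
            trb[reuse] <- csf_keys$trb[src]
            shared[reuse] <- TRUE
          }
        }
        if (comp == "CSF") csf_keys <- data.frame(tra = tra, trb = trb)

        cell_order <- sample(nT)
        clone_of_cell <- integer(nT)
        clone_of_cell[cell_order] <- rep(seq_len(n_clones), sizes)
        sample_id <- rep_cells$sample_id[1]
        for (chain in c("TRA", "TRB")) {
          nt <- if (chain == "TRA") tra else trb
          k <- k + 1L
          contigs[[k]] <- data.frame(
            barcode = rep_cells$cell_id,
            is_cell = "true",
            chain = chain,
            v_gene = sprintf("%sV%d", chain, 1 + clone_of_cell %% 30),
            j_gene = sprintf("%sJ%d", chain, 1 + clone_of_cell %% 12),
            cdr3 = translate_nt(nt[clone_of_cell]),
            cdr3_nt = nt[clone_of_cell],
            reads = 30L * (1L + clone_of_cell %% 8L),
            umis = 1L + clone_of_cell %% 8L,
            raw_clonotype_id = paste0("clonotype", clone_of_cell),
            sample_id = sample_id,
            subject = sub,
            compartment = comp,
            stringsAsFactors = FALSE)
        }
        truth[[length(truth) + 1L]] <- data.frame(
          subject = sub, compartment = comp, clone = seq_len(n_clones),
          tra_nt = tra, trb_nt = trb, size = sizes, shared = shared,
          stringsAsFactors = FALSE)
      }
    }
    contigs <- do.call(rbind, contigs)
    rownames(contigs) <- NULL
    list(contigs = contigs, truth = do.call(rbind, truth))
  })
}
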