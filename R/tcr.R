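#' Call clones from paired-chain contigs
#'
#' A clone is a group of cells sharing identical CDR3 sequences in both the
#' TCR alpha and beta chains — nucleotide sequences by default, amino-acid
#' sequences with `mode = "aa"`. Within each cell, multiple contigs of the
#' same chain are resolved to the highest-UMI contig (ties broken by the
#' lexicographically smallest nucleotide CDR3); cells lacking either chain
#' are excluded from paired-clone analyses and reported separately. Records
#' with malformed nucleotide CDR3s (characters outside A/C/G/T) are rejected
#' with a message.
#'
#' @param contigs data.frame in CellRanger `filtered_contig_annotations.csv`
#'   dialect: at least `barcode`, `chain`, `cdr3`, `cdr3_nt`, `umis`;
#'   `sample_id` and `compartment` are carried through when present.
#' @param mode clone key space: `"nt"` (default) or `"aa"`.
#' @return object of class `clone_calls`: list with `cells` (per-cell clone
#'   assignment with `clone_id`, key chains, and `size`), `clones` (one row
#'   per clone), `unpaired` (cells lacking a chain), and the `mode`.
#' @export
call_clones <- function(contigs, mode = c("nt", "aa")) {
  mode <- match.arg(mode)
  need <- c("barcode", "chain", "cdr3", "cdr3_nt", "umis")
  stopifnot(all(need %in% colnames(contigs)))
  bad <- grepl("[^ACGT]", contigs$cdr3_nt)
  if (any(bad)) {
    message("rejecting ", sum(bad), " contig(s) with malformed CDR3 nt")
    contigs <- contigs[!bad, , drop = FALSE]
  }
  contigs <- contigs[contigs$chain %in% c("TRA", "TRB"), , drop = FALSE]
  has_sample <- "sample_id" %in% colnames(contigs)
  cell <- if (has_sample) paste(contigs$sample_id, contigs$barcode, sep = "::")
          else contigs$barcode

  # highest-UMI contig per (cell, chain); tie -> smallest cdr3_nt
  ord <- order(cell, contigs$chain, -contigs$umis, contigs$cdr3_nt)
  contigs <- contigs[ord, , drop = FALSE]
  cell <- cell[ord]
  keep <- !duplicated(paste(cell, contigs$chain))
  contigs <- contigs[keep, , drop = FALSE]
  cell <- cell[keep]

  seqcol <- if (mode == "nt") "cdr3_nt" else "cdr3"
  tra <- contigs[contigs$chain == "TRA", , drop = FALSE]
  trb <- contigs[contigs$chain == "TRB", , drop = FALSE]
  tra_cell <- cell[contigs$chain == "TRA"]
  trb_cell <- cell[contigs$chain == "TRB"]

  paired <- intersect(tra_cell, trb_cell)
  meta_of <- function(cells_vec, src, src_cell) {
    src[match(cells_vec, src_cell), , drop = FALSE]
  }
  ta <- meta_of(paired, tra, tra_cell)
  tb <- meta_of(paired, trb, trb_cell)
  key <- paste(ta[[seqcol]], tb[[seqcol]], sep = "_")
  h <- fnv1a32(key)
  clone_id <- sprintf("cl%04x%04x", as.integer(h %/% 65536),
                      as.integer(h %% 65536))

  cells <- data.frame(cell = paired, barcode = ta$barcode,
                      clone_id = clone_id,
                      tra = ta[[seqcol]], trb = tb[[seqcol]],
                      stringsAsFactors = FALSE)
  if (has_sample) {
    cells$sample_id <- ta$sample_id
    if ("compartment" %in% colnames(ta)) cells$compartment <- ta$compartment
  }
  sizes <- table(cells$clone_id)
  cells$size <- as.integer(sizes[cells$clone_id])

  first <- !duplicated(cells$clone_id)
  clones <- data.frame(clone_id = cells$clone_id[first],
                       tra = cells$tra[first], trb = cells$trb[first],
                       size = cells$size[first], stringsAsFactors = FALSE)
  if (has_sample) {
    clones$samples <- vapply(clones$clone_id, function(id)
      paste(sort(unique(cells$sample_id[cells$clone_id == id])),
            collapse = ";"), character(1))
    if ("compartment" %in% colnames(cells))
      clones$compartments <- vapply(clones$clone_id, function(id)
        paste(sort(unique(cells$compartment[cells$clone_id == id])),
              collapse = ";"), character(1))
  }
  unpaired_cells <- setdiff(union(tra_cell, trb_cell), paired)
  structure(list(cells = cells,
                 clones = clones[order(-clones$size, clones$clone_id), ],
                 unpaired = data.frame(cell = unpaired_cells,
                                       stringsAsFactors = FALSE),
                 mode = mode),
            class = "clone_calls")
}

#' Clonal space occupancy
#'
#' Each clone's relative proportion is its size over the total paired-cell
#' count; clones fall into half-open relative-proportion bins (lo, hi], and a
#' bin's occupancy is the summed proportion of its member clones, so
#' occupancies total 1.
#'
#' @param calls a `clone_calls` object (or a data.frame with a `size` column).
#' @param bins increasing cut points; default (0, 1e-4, 1e-3, 0.01, 0.1, 1].
#' @return data.frame (bin, lo, hi, n_clones, occupancy).
#' @export
clonal_occupancy <- function(calls, bins = c(0, 1e-4, 1e-3, 0.01, 0.1, 1)) {
  sizes <- if (inherits(calls, "clone_calls")) calls$clones$size else calls$size
  if (!length(sizes)) stop("empty repertoire")
  p <- sizes / sum(sizes)
  idx <- findInterval(p, bins, left.open = TRUE)  # bin i = (bins[i], bins[i+1]]
  nb <- length(bins) - 1L
  occupancy <- vapply(seq_len(nb), function(i) sum(p[idx == i]), numeric(1))
  data.frame(bin = sprintf("(%g,%g]", bins[-length(bins)], bins[-1]),
             lo = bins[-length(bins)], hi = bins[-1],
             n_clones = as.integer(tabulate(idx, nb)),
             occupancy = occupancy, stringsAsFactors = FALSE)
}

#' Stratify cells by clonal expansion
#'
#' Cells in clones of size >= `threshold` (within the repertoire being
#' analyzed) are "high"-clonal; smaller clones are "low".
#'
#' @param calls a `clone_calls` object.
#' @param threshold clone-size cutoff (20, inclusive for "high").
#' @return character vector ("high"/"low"), one entry per row of
#'   `calls$cells`.
#' @export
stratify_clonality <- function(calls, threshold = 20L) {
  stopifnot(inherits(calls, "clone_calls"))
  ifelse(calls$cells$size >= threshold, "high", "low")
}

#' Trace clones shared between two repertoires
#'
#' Intersects the clone keys of two repertoires called in the same mode
#' (e.g. a subject's blood and CSF) and reports per-side clone sizes.
#'
#' @param rep_a,rep_b `clone_calls` objects with matching `mode`.
#' @return data.frame (tra, trb, size_a, size_b); empty when the repertoires
#'   are disjoint.
#' @export
trace_clones <- function(rep_a, rep_b) {
  stopifnot(inherits(rep_a, "clone_calls"), inherits(rep_b, "clone_calls"))
  if (!identical(rep_a$mode, rep_b$mode))
    stop("repertoires were clone-called in different modes: ",
         rep_a$mode, " vs ", rep_b$mode)
  merge(rep_a$clones[, c("tra", "trb", "size")],
        rep_b$clones[, c("tra", "trb", "size")],
        by = c("tra", "trb"), suffixes = c("_a", "_b"))
}

#' Pairwise clonal overlap across repertoires
#'
#' Jaccard overlap of clone-key sets: entry (i, j) is |keys_i & keys_j| /
#' |keys_i | keys_j|. The diagonal is 1 by convention, including for empty
#' repertoires (logged).
#'
#' @param repertoires named list of `clone_calls` objects (>= 2).
#' @param metric currently `"jaccard"`.
#' @return symmetric numeric matrix with unit diagonal.
#' @export
overlap_matrix <- function(repertoires, metric = "jaccard") {
  metric <- match.arg(metric, "jaccard")
  stopifnot(length(repertoires) >= 2L)
  keys <- lapply(repertoires, function(r) {
    stopifnot(inherits(r, "clone_calls"))
    unique(paste(r$clones$tra, r$clones$trb, sep = "_"))
  })
  if (any(lengths(keys) == 0L))
    message("empty repertoire(s): ",
            paste(names(keys)[lengths(keys) == 0L], collapse = ", "))
  n <- length(keys)
  m <- diag(1, n)
  dimnames(m) <- list(names(repertoires), names(repertoires))
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    u <- length(union(keys[[i]], keys[[j]]))
    m[i, j] <- m[j, i] <- if (u == 0L) 0 else
      length(intersect(keys[[i]], keys[[j]])) / u
  }
  m
}
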