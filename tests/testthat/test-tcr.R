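make_contigs <- function(barcodes, tra, trb, umis_a = 3, umis_b = 3) {
  rbind(
    data.frame(barcode = barcodes, chain = "TRA", cdr3 = translate_nt(tra),
               cdr3_nt = tra, umis = umis_a, stringsAsFactors = FALSE),
    data.frame(barcode = barcodes, chain = "TRB", cdr3 = translate_nt(trb),
               cdr3_nt = trb, umis = umis_b, stringsAsFactors = FALSE))
}

test_that("clone calling groups by paired-chain identity", {
  a <- "TGTGCAAGC"; b <- "TGTGCAAGT"   # synonymous third-position change
  contigs <- make_contigs(c("c1", "c2", "c3", "c4"),
                          tra = c(a, a, a, a),
                          trb = c(a, a, a, b))
  calls <- call_clones(contigs)
  expect_equal(sort(calls$clones$size), c(1L, 3L))
  expect_equal(length(unique(calls$cells$clone_id)), 2)
  # amino-acid mode coarsens the two nt clones into one (synonymous codons)
  aa <- call_clones(contigs, mode = "aa")
  expect_equal(nrow(aa$clones), 1)
  expect_equal(aa$clones$size, 4L)
})

test_that("within-cell contig conflicts resolve by UMI then lexicographic order", {
  contigs <- rbind(
    data.frame(barcode = "c1", chain = "TRA", cdr3 = "X", cdr3_nt = "AAATTT",
               umis = 2),
    data.frame(barcode = "c1", chain = "TRA", cdr3 = "X", cdr3_nt = "CCCGGG",
               umis = 9),
    data.frame(barcode = "c1", chain = "TRB", cdr3 = "X", cdr3_nt = "GGGAAA",
               umis = 5),
    data.frame(barcode = "c1", chain = "TRB", cdr3 = "X", cdr3_nt = "AAACCC",
               umis = 5))
  calls <- call_clones(contigs)
  expect_equal(calls$cells$tra, "CCCGGG")   # highest UMI wins
  expect_equal(calls$cells$trb, "AAACCC")   # tie: smallest sequence wins
})

test_that("unpaired cells are excluded but reported, malformed contigs rejected", {
  contigs <- rbind(
    make_contigs("c1", "AAATTT", "CCCGGG"),
    data.frame(barcode = "c2", chain = "TRA", cdr3 = "K", cdr3_nt = "AAAAAA",
               umis = 1, stringsAsFactors = FALSE),
    data.frame(barcode = "c3", chain = "TRB", cdr3 = "K", cdr3_nt = "AANAAA",
               umis = 1, stringsAsFactors = FALSE))
  expect_message(calls <- call_clones(contigs), "malformed")
  expect_equal(nrow(calls$cells), 1)
  expect_true("c2" %in% calls$unpaired$cell)
  expect_equal(sum(calls$cells$size), 1)  # clone sizes sum to paired cells
})

test_that("clone assignment equals the O(n^2) brute-force grouping on 200 cells", {
  set.seed(30)
  pool_a <- replicate(40, paste(sample(c("A", "C", "G", "T"), 9,
                                       replace = TRUE), collapse = ""))
  pool_b <- replicate(40, paste(sample(c("A", "C", "G", "T"), 9,
                                       replace = TRUE), collapse = ""))
  idx <- sample(40, 200, replace = TRUE)
  tra <- pool_a[idx]; trb <- pool_b[idx]
  contigs <- make_contigs(sprintf("c%03d", 1:200), tra, trb)
  calls <- call_clones(contigs)
  impl <- calls$cells$clone_id[match(sprintf("c%03d", 1:200),
                                     calls$cells$barcode)]
  brute <- brute_force_clones(tra, trb)
  expect_equal(match(impl, unique(impl)), brute)
  expect_equal(sum(calls$clones$size), 200)
})

test_that("clonal occupancy bins partition the repertoire", {
  # single clone: all occupancy in the top bin
  one <- clonal_occupancy(data.frame(size = 50))
  expect_equal(one$occupancy[one$bin == "(0.1,1]"], 1)
  expect_equal(sum(one$occupancy), 1)

  # N singletons: everything in the bin holding 1/N
  many <- clonal_occupancy(data.frame(size = rep(1, 500)))
  expect_equal(many$occupancy[many$bin == "(0.001,0.01]"], 1)

  # power-law fixture equals brute-force summation, and occupancy is
  # invariant to duplicating every cell
  set.seed(31)
  sizes <- rimflow:::draw_clone_sizes(3000, 400, alpha = 2)
  occ <- clonal_occupancy(data.frame(size = sizes))
  p <- sizes / sum(sizes)
  bins <- c(0, 1e-4, 1e-3, 0.01, 0.1, 1)
  brute <- sapply(seq_len(5), function(i)
    sum(p[p > bins[i] & p <= bins[i + 1]]))
  expect_equal(occ$occupancy, brute)
  expect_equal(sum(occ$occupancy), 1)
  occ2 <- clonal_occupancy(data.frame(size = sizes * 2L))
  expect_equal(occ2$occupancy, occ$occupancy)
  expect_error(clonal_occupancy(data.frame(size = integer(0))), "empty")
})

test_that("high/low clonality splits exactly at twenty", {
  sizes <- c(20, 19, 1)
  calls <- structure(list(cells = data.frame(size = sizes)),
                     class = "clone_calls")
  expect_equal(stratify_clonality(calls), c("high", "low", "low"))
  singletons <- structure(list(cells = data.frame(size = rep(1, 5))),
                          class = "clone_calls")
  expect_true(all(stratify_clonality(singletons) == "low"))
})

test_that("cross-compartment tracing finds exactly the planted clones", {
  cfg <- sim_config(seed = 33, n_genes = 150, n_samples_per_group = 1,
                    n_cells_per_sample = 400,
                    tcr = list(n_clones = 30L, sharing = 1))
  co <- simulate_cohort(cfg)
  sim <- simulate_tcr(co, cfg)
  csf <- call_clones(sim$contigs[sim$contigs$compartment == "CSF", ])
  pbmc <- call_clones(sim$contigs[sim$contigs$compartment == "PBMC", ])
  shared <- trace_clones(csf, pbmc)
  planted <- sim$truth[sim$truth$shared, ]
  expect_equal(sort(paste(shared$tra, shared$trb)),
               sort(paste(planted$tra_nt, planted$trb_nt)))
  # reported sizes match the truth on each side
  csf_truth <- sim$truth[sim$truth$compartment == "CSF", ]
  m <- match(paste(shared$tra, shared$trb),
             paste(csf_truth$tra_nt, csf_truth$trb_nt))
  expect_equal(shared$size_a, csf_truth$size[m])
  # tracing is symmetric in its key set
  rev <- trace_clones(pbmc, csf)
  expect_setequal(paste(rev$tra, rev$trb), paste(shared$tra, shared$trb))
  expect_error(trace_clones(csf, call_clones(sim$contigs, mode = "aa")),
               "different modes")
})

test_that("the overlap matrix equals set arithmetic", {
  mk <- function(tra, trb) call_clones(
    make_contigs(sprintf("c%d", seq_along(tra)), tra, trb))
  r1 <- mk(c("AAATTT", "CCCGGG"), c("TTTAAA", "GGGCCC"))
  r2 <- mk(c("AAATTT", "ACGACG"), c("TTTAAA", "CGTCGT"))
  r3 <- mk("GGGGGG", "CCCCCC")
  m <- overlap_matrix(list(a = r1, b = r2, c = r3))
  expect_equal(diag(m), c(a = 1, b = 1, c = 1))
  expect_equal(m["a", "b"], 1 / 3)     # 1 shared key of 3 distinct
  expect_equal(m["a", "c"], 0)
  expect_true(isSymmetric(m))
  expect_equal(unname(overlap_matrix(list(x = r1, y = r1))["x", "y"]), 1)
})

test_that("nucleotide translation follows the standard code", {
  expect_equal(translate_nt(c("ATGAAA", "TTTGGG")), c("MK", "FG"))
  expect_error(translate_nt("ATGA"), "multiple of 3")
  # simulated CDR3s are built from sense codons: no stops anywhere
  cfg <- sim_config(seed = 34, n_genes = 150, n_samples_per_group = 1,
                    n_cells_per_sample = 200, tcr = list(n_clones = 15L))
  sim <- simulate_tcr(simulate_cohort(cfg), cfg)
  expect_false(any(grepl("\\*", sim$contigs$cdr3)))
  # nt clones map into exactly one aa clone each (coarsening invariant)
  nt <- call_clones(sim$contigs)
  aa <- call_clones(sim$contigs, mode = "aa")
  map <- tapply(aa$cells$clone_id, nt$cells$clone_id,
                function(x) length(unique(x)))
  expect_true(all(map == 1))
})
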