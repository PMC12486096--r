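# Shared fixtures and independent brute-force oracles. Oracles are written as
# plain per-record loops so they stay independent of the vectorized
# implementations they check.

# per-cell QC fixture with injected outliers on every metric
random_qc_fixture <- function(n = 1000L, seed = 42L) {
  set.seed(seed)
  qc <- data.frame(
    cell_id = sprintf("c%04d", seq_len(n)),
    sample_id = sample(paste0("s", 1:4), n, replace = TRUE),
    n_genes = round(rnorm(n, 1200, 300)),
    n_umi = round(rnorm(n, 3500, 800)),
    pct_mito = pmax(0, rnorm(n, 1, 0.6)),
    doublet_score = rgamma(n, 2, scale = 0.05))
  out <- sample(n, 60)
  qc$n_genes[out[1:15]] <- sample(c(50:199, 5001:8000), 15)
  qc$pct_mito[out[16:30]] <- runif(15, 2.1, 15)
  qc$n_umi[out[31:45]] <- sample(c(50:499, 9000:12000), 15)
  qc$doublet_score[out[46:60]] <- runif(15, 0.5, 1)
  qc$n_genes <- pmax(qc$n_genes, 10)
  qc$n_umi <- pmax(qc$n_umi, qc$n_genes)
  qc
}

# brute-force per-cell evaluation of the three staged filters
brute_force_qc <- function(qc, sd_mult = 2) {
  keep1 <- logical(nrow(qc))
  for (i in seq_len(nrow(qc)))
    keep1[i] <- qc$n_genes[i] >= 200 && qc$n_genes[i] <= 5000 &&
      qc$pct_mito[i] < 10
  pool <- qc[keep1, ]
  g_hi <- mean(pool$n_genes) + sd_mult * sd(pool$n_genes)
  u_hi <- mean(pool$n_umi) + sd_mult * sd(pool$n_umi)
  keep2 <- keep1
  for (i in which(keep1))
    keep2[i] <- !(qc$n_genes[i] > g_hi || qc$n_genes[i] < 250 ||
                    qc$n_umi[i] > u_hi || qc$n_umi[i] < 500 ||
                    qc$pct_mito[i] > 2)
  keep3 <- keep2
  for (s in unique(qc$sample_id)) {
    idx <- which(keep2 & qc$sample_id == s)
    if (length(idx) < 2) next
    thr <- mean(qc$doublet_score[idx]) + sd_mult * sd(qc$doublet_score[idx])
    for (i in idx) keep3[i] <- qc$doublet_score[i] <= thr
  }
  list(per_sample = keep1, merged = keep2, doublet = keep3)
}

# O(n^2) pairwise-identity clone grouping: same clone iff both chains match
brute_force_clones <- function(tra, trb) {
  n <- length(tra)
  grp <- seq_len(n)
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    if (tra[i] == tra[j] && trb[i] == trb[j]) grp[j] <- grp[i]
  }
  match(grp, unique(grp))
}

# label-only cell table for composition tests: n cells per condition drawn
# multinomially from per-condition cluster proportions
label_cells <- function(n_per_cond, props_a, props_b, seed) {
  set.seed(seed)
  data.frame(
    cluster = c(sample(names(props_a), n_per_cond, replace = TRUE,
                       prob = props_a),
                sample(names(props_b), n_per_cond, replace = TRUE,
                       prob = props_b)),
    group = rep(c("A", "B"), each = n_per_cond),
    stringsAsFactors = FALSE)
}

# small dense log-normalized matrix with named genes
toy_norm_matrix <- function(n_genes = 30, n_cells = 60, seed = 1) {
  set.seed(seed)
  m <- matrix(rpois(n_genes * n_cells, 5), n_genes, n_cells,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              sprintf("c%02d", seq_len(n_cells))))
  log_normalize(m)
}
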