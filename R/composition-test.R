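# log2 fold-difference of per-cluster proportions, with a 0.5-cell
# pseudo-count added to both conditions for clusters empty in either one.
# Written as a difference of logs so that swapping the conditions negates the
# statistic bit-exactly (a - b == -(b - a) in floating point, unlike log of a
# reciprocal), which keeps the permutation p-value identical either way.
log2_fd <- function(count_a, count_b, n_a, n_b) {
  z <- count_a == 0 | count_b == 0
  ca <- count_a + 0.5 * z
  cb <- count_b + 0.5 * z
  log2(cb / n_b) - log2(ca / n_a)
}

#' Permutation test for cell-composition differences
#'
#' For every cluster, the observed log2 fold-difference of proportions
#' (condition B over condition A) is compared with a null built by permuting
#' condition labels over cells (condition sizes preserved). The two-sided
#' permutation p-value is (1 + #permutations with |null log2FD| >= |observed|)
#' / (n_perm + 1); a percentile bootstrap (cells resampled with replacement
#' within condition) gives the confidence interval, and Benjamini-Hochberg
#' FDR is applied across the clusters of this one comparison. Clusters absent
#' from one condition receive a 0.5-cell pseudo-count in both conditions
#' (flagged in the output); clusters absent from both are dropped.
#'
#' Swapping `cond_a` and `cond_b` at the same seed negates every estimate
#' exactly, mirrors the confidence interval, and leaves p-values unchanged.
#'
#' @param cells per-cell metadata.
#' @param cond_a,cond_b condition labels to compare (A is the reference).
#' @param condition_col,cluster_col metadata columns holding the condition and
#'   cluster labels.
#' @param n_perm permutations (1000).
#' @param n_boot bootstrap resamples for the CI (1000; 0 skips the CI).
#' @param seed integer seed.
#' @param fd_threshold,fdr_threshold significance rule passed to
#'   [classify_shifts()].
#' @return data.frame (cluster, n_a, n_b, prop_a, prop_b, obs_log2FD, ci_low,
#'   ci_high, p_perm, fdr, pseudo, significant).
#' @export
proportion_test <- function(cells, cond_a, cond_b, condition_col = "group",
                            cluster_col = "cluster", n_perm = 1000L,
                            n_boot = 1000L, seed = 1L,
                            fd_threshold = 0.41, fdr_threshold = 0.05) {
  cond <- cells[[condition_col]]
  keep <- cond %in% c(cond_a, cond_b)
  if (!any(cond == cond_a) || !any(cond == cond_b))
    stop("both conditions must be present")
  cond <- cond[keep]
  clusters <- sort(unique(cells[[cluster_col]][keep]))
  ci <- match(cells[[cluster_col]][keep], clusters)
  K <- length(clusters)
  n <- length(ci)

  # process conditions in sorted label order so the RNG stream is identical
  # whichever direction the comparison is run in
  lev <- sort(c(cond_a, cond_b))
  first_is_a <- lev[1] == cond_a
  idx1 <- which(cond == lev[1])
  idx2 <- which(cond == lev[2])
  cnt1 <- tabulate(ci[idx1], K); cnt2 <- tabulate(ci[idx2], K)
  cnt_a <- if (first_is_a) cnt1 else cnt2
  cnt_b <- if (first_is_a) cnt2 else cnt1
  n_a <- sum(cnt_a); n_b <- sum(cnt_b)
  obs <- log2_fd(cnt_a, cnt_b, n_a, n_b)

  with_seed(child_seed(seed, "proportion_test"), {
    null_abs_ge <- integer(K)
    n1 <- length(idx1)
    for (r in seq_len(n_perm)) {
      pick1 <- sample.int(n, n1)
      c1 <- tabulate(ci[pick1], K)
      c2 <- tabulate(ci, K) - c1
      pa <- if (first_is_a) c1 else c2
      pb <- if (first_is_a) c2 else c1
      null_abs_ge <- null_abs_ge +
        (abs(log2_fd(pa, pb, n_a, n_b)) >= abs(obs))
    }
    p_perm <- (1 + null_abs_ge) / (n_perm + 1)

    ci_low <- ci_high <- rep(NA_real_, K)
    if (n_boot > 0L) {
      boot <- matrix(NA_real_, K, n_boot)
      for (r in seq_len(n_boot)) {
        b1 <- tabulate(ci[sample(idx1, length(idx1), replace = TRUE)], K)
        b2 <- tabulate(ci[sample(idx2, length(idx2), replace = TRUE)], K)
        ba <- if (first_is_a) b1 else b2
        bb <- if (first_is_a) b2 else b1
        boot[, r] <- log2_fd(ba, bb, n_a, n_b)
      }
      qs <- apply(boot, 1, stats::quantile, probs = c(0.025, 0.975),
                  names = FALSE)
      ci_low <- qs[1, ]; ci_high <- qs[2, ]
    }

    res <- data.frame(
      cluster = clusters, n_a = cnt_a, n_b = cnt_b,
      prop_a = cnt_a / n_a, prop_b = cnt_b / n_b,
      obs_log2FD = obs, ci_low = ci_low, ci_high = ci_high,
      p_perm = p_perm, fdr = stats::p.adjust(p_perm, method = "BH"),
      pseudo = cnt_a == 0 | cnt_b == 0, stringsAsFactors = FALSE)
    res <- res[!(res$n_a == 0 & res$n_b == 0), , drop = FALSE]
    res$significant <- res$cluster %in%
      classify_shifts(res, fd_threshold, fdr_threshold)
    rownames(res) <- NULL
    res
  })
}

#' Flag significant composition shifts
#'
#' A cluster is significant when |log2FD| strictly exceeds `fd_threshold` and
#' its FDR is strictly below `fdr_threshold`.
#'
#' @param results output of [proportion_test()].
#' @param fd_threshold log2 fold-difference threshold (0.41).
#' @param fdr_threshold FDR threshold (0.05).
#' @return character vector of significant cluster labels.
#' @export
classify_shifts <- function(results, fd_threshold = 0.41,
                            fdr_threshold = 0.05) {
  results$cluster[abs(results$obs_log2FD) > fd_threshold &
                    results$fdr < fdr_threshold]
}
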