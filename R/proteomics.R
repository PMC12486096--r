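#' Cyclic loess normalization of an NPX matrix
#'
#' Cross-sample normalization by pairwise cyclic loess (every sample pair's
#' M-vs-A relationship is loess-fit and half the fit subtracted from each
#' side, cycled a fixed number of iterations), followed by clamping negative
#' entries to zero. Assays that are entirely missing are dropped with a
#' message.
#'
#' @param m assays x samples matrix of log2 NPX values (>= 2 samples).
#' @param span loess span (0.7).
#' @param iterations cyclic passes (3).
#' @return the normalized, clamped matrix; attribute `"prenorm"` keeps the
#'   input (after all-missing assay removal) for pre/post inspection.
#' @export
cyclic_loess_normalize <- function(m, span = 0.7, iterations = 3L) {
  stopifnot(is.matrix(m), ncol(m) >= 2L)
  all_na <- apply(m, 1, function(x) all(is.na(x)))
  if (any(all_na)) {
    message("dropping ", sum(all_na), " all-missing assay(s)")
    m <- m[!all_na, , drop = FALSE]
  }
  out <- limma::normalizeCyclicLoess(m, span = span, iterations = iterations,
                                     method = "pairs")
  dimnames(out) <- dimnames(m)
  out[out < 0] <- 0
  attr(out, "prenorm") <- m
  out
}

#' Noise-floor filter for NPX assays
#'
#' Per-assay mean and coefficient of variation are computed on the linear
#' scale (2^NPX) and the CV-vs-log2(mean) relationship is lowess-smoothed.
#' Over the upper half of assay means the smoothed curve is close to linear;
#' its local slope there defines the reference behavior (median and MAD).
#' Scanning from high to low mean, the noise cutoff is the mean at which the
#' smoothed curve's local slope first drops below the reference median by
#' more than max(`k` x MAD, `min_drop`) — the point where the linear
#' relationship with CV is grossly lost and the noise floor takes over. The
#' absolute floor `min_drop` keeps smoothing wiggle on a flat CV profile
#' from firing the rule. Assays with mean strictly below the cutoff are
#' removed; if no breakpoint is found the cutoff is -Inf and everything is
#' retained.
#'
#' @param m assays x samples log2 NPX matrix (>= 10 assays).
#' @param k MAD multiplier for the breakpoint rule (3).
#' @param min_drop absolute minimum slope departure, in CV units per log2
#'   mean (0.02).
#' @param lowess_f lowess smoother span (2/3).
#' @return list with `retained` (filtered matrix), `cutoff` (linear-scale
#'   mean), and `diagnostics` (per-assay mean, cv, smoothed cv, local slope,
#'   retained flag).
#' @export
noise_filter <- function(m, k = 3, min_drop = 0.02, lowess_f = 2/3) {
  stopifnot(is.matrix(m), nrow(m) >= 10L)
  lin <- 2^m
  mu <- rowMeans(lin)
  cv <- apply(lin, 1, stats::sd) / mu
  lmu <- log2(mu)
  ord <- order(lmu)
  sm <- stats::lowess(lmu[ord], cv[ord], f = lowess_f)
  # central-difference local slope of the smoothed curve along log2(mean)
  ns <- length(sm$x)
  lo <- c(1, seq_len(ns - 1)); hi <- c(seq(2, ns), ns)
  slope_sorted <- (sm$y[hi] - sm$y[lo]) / pmax(sm$x[hi] - sm$x[lo], 1e-9)
  smoothed <- numeric(length(mu)); smoothed[ord] <- sm$y
  slope <- numeric(length(mu)); slope[ord] <- slope_sorted
  upper <- lmu >= stats::median(lmu)
  ref <- stats::median(slope[upper])
  mad_u <- stats::mad(slope[upper])
  violate <- slope < ref - max(k * mad_u, min_drop) & !upper
  cutoff <- if (any(violate)) max(mu[violate]) else -Inf
  retained_mask <- mu >= cutoff
  list(retained = m[retained_mask, , drop = FALSE],
       cutoff = cutoff,
       diagnostics = data.frame(assay = rownames(m), mean = mu, cv = cv,
                                smoothed_cv = smoothed, slope = slope,
                                retained = retained_mask,
                                stringsAsFactors = FALSE))
}

#' Covariate-adjusted differential abundance (ANCOVA)
#'
#' Fits, per assay, the ordinary least-squares model
#' `NPX ~ group + sex + age`. For a two-group contrast the group coefficient
#' is the adjusted log2 fold-change with its t-test p-value; with more than
#' two groups the omnibus F p-value is reported together with the Tukey HSD
#' post-hoc p-value for the requested pair. The adjusted matrix has the age
#' and sex effects (centered at their means) removed, leaving group structure
#' intact. An assay is significant when |adjusted log2 fold-change| exceeds
#' `fold_threshold` and its (post-hoc, when applicable) p-value is below
#' `alpha`; the default threshold 0.58 is the 1.5-fold dialect, with 0.3219
#' (1.25-fold) used for ratio analyses. BH adjustment across assays of the
#' primary p-value is reported alongside.
#'
#' @param m assays x samples log2 NPX matrix.
#' @param covariates data.frame (sample_id, group, age, sex) covering every
#'   column of `m`.
#' @param contrast character pair c(reference, test); defaults to the first
#'   two group levels in the covariate table.
#' @param fold_threshold log2 fold-change threshold (0.58; use 0.3219 for the
#'   1.25-fold dialect).
#' @param alpha p-value threshold (0.05).
#' @return list with `results` (per-assay data.frame), `adjusted` (covariate-
#'   adjusted matrix), and `contrast`.
#' @export
ancova_differential <- function(m, covariates, contrast = NULL,
                                fold_threshold = 0.58, alpha = 0.05) {
  stopifnot(is.matrix(m), all(colnames(m) %in% covariates$sample_id))
  cov <- covariates[match(colnames(m), covariates$sample_id), ]
  stopifnot(!anyNA(cov$group), !anyNA(cov$age), !anyNA(cov$sex))
  lev <- unique(cov$group)
  if (is.null(contrast)) contrast <- lev[1:2]
  stopifnot(length(contrast) == 2L, all(contrast %in% lev))
  grp <- stats::relevel(factor(cov$group, levels = lev), ref = contrast[1])
  sexI <- as.numeric(factor(cov$sex)) - 1
  age <- cov$age
  multi <- length(lev) > 2L
  coef_name <- paste0("grp", contrast[2])
  tukey_name_fwd <- paste(contrast[2], contrast[1], sep = "-")
  tukey_name_rev <- paste(contrast[1], contrast[2], sep = "-")

  res <- vector("list", nrow(m))
  adjusted <- m
  for (i in seq_len(nrow(m))) {
    y <- m[i, ]
    fit <- stats::lm(y ~ grp + sexI + age)
    cf <- stats::coef(fit)
    if (is.na(cf[[coef_name]])) {
      message("assay ", rownames(m)[i], " skipped: rank-deficient design")
      res[[i]] <- data.frame(assay = rownames(m)[i],
                             adjusted_log2fc = NA_real_, p = NA_real_,
                             posthoc_p = NA_real_, stringsAsFactors = FALSE)
      next
    }
    b_sex <- if (is.na(cf[["sexI"]])) 0 else cf[["sexI"]]
    b_age <- if (is.na(cf[["age"]])) 0 else cf[["age"]]
    adj_y <- y - b_sex * (sexI - mean(sexI)) - b_age * (age - mean(age))
    adjusted[i, ] <- adj_y
    if (!multi) {
      sm <- stats::summary.lm(fit)$coefficients
      res[[i]] <- data.frame(assay = rownames(m)[i],
                             adjusted_log2fc = cf[[coef_name]],
                             p = sm[coef_name, "Pr(>|t|)"],
                             posthoc_p = NA_real_, stringsAsFactors = FALSE)
    } else {
      p_omni <- stats::anova(fit)["grp", "Pr(>F)"]
      # Tukey on the covariate-adjusted values: TukeyHSD on a model with
      # continuous covariates compares unadjusted group means against the
      # covariate-reduced error term, which inflates type-I error
      tk <- stats::TukeyHSD(stats::aov(adj_y ~ grp), which = "grp")$grp
      ph <- if (tukey_name_fwd %in% rownames(tk))
        tk[tukey_name_fwd, "p adj"] else tk[tukey_name_rev, "p adj"]
      res[[i]] <- data.frame(assay = rownames(m)[i],
                             adjusted_log2fc = cf[[coef_name]],
                             p = p_omni, posthoc_p = ph,
                             stringsAsFactors = FALSE)
    }
  }
  results <- do.call(rbind, res)
  results$p_adj <- stats::p.adjust(results$p, method = "BH")
  decisive_p <- if (multi) results$posthoc_p else results$p
  results$significant <- !is.na(results$adjusted_log2fc) &
    abs(results$adjusted_log2fc) > fold_threshold & decisive_p < alpha
  rownames(results) <- NULL
  list(results = results, adjusted = adjusted, contrast = contrast)
}

#' CSF:serum compartmentalization ratios
#'
#' Since NPX values are log2-scale, the per-assay CSF:serum ratio is the
#' element-wise difference CSF NPX - serum NPX over the assays common to both
#' matrices. Sample columns must align exactly; any mismatch is a hard error
#' (no silent reindexing). Downstream ANCOVA of the ratio matrix uses the
#' 1.25-fold dialect (threshold 0.3219).
#'
#' @param csf,serum assays x samples log2 NPX matrices with identical sample
#'   columns.
#' @return matrix of ratios over the common assays.
#' @export
csf_serum_ratio <- function(csf, serum) {
  if (!identical(colnames(csf), colnames(serum)))
    stop("CSF and serum samples are not aligned")
  common <- intersect(rownames(csf), rownames(serum))
  if (!length(common)) stop("no common assays between compartments")
  csf[common, , drop = FALSE] - serum[common, , drop = FALSE]
}

#' Preprocess raw Ella analyte values
#'
#' Raw pg/mL values are pedestaled and log2-transformed:
#' `log2(raw + pedestal)`. Subsequent modeling reuses
#' [ancova_differential()].
#'
#' @param raw matrix or vector of non-negative pg/mL values.
#' @param pedestal additive pedestal (1).
#' @return log2-transformed values of the same shape.
#' @export
ella_preprocess <- function(raw, pedestal = 1) {
  if (any(raw < 0)) stop("raw analyte values must be non-negative")
  log2(raw + pedestal)
}
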