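#' Simulate matched CSF and serum NPX matrices
#'
#' Per-assay log2 abundances are baseline + age and sex covariate effects +
#' a per-group effect + noise. The noise standard deviation is implied by a
#' linear-scale coefficient of variation CV(mu) = a + b/sqrt(mu), evaluated at
#' the assay's baseline linear mean, so low-abundance assays sit on a rising
#' noise floor (the structure the [noise_filter()] cutoff is designed to
#' detect). Assays listed in `csf_only_assay_ids` receive the group effect in
#' the CSF matrix only, planting a CSF:serum ratio contrast; both matrices
#' share sample ids, ages, and sexes.
#'
#' @param config a [sim_config()]; the `npx` sub-list holds all parameters.
#' @return list with `csf` and `serum` (assays x samples log2 NPX matrices),
#'   `covariates` (sample_id, group, age, sex), and `truth`.
#' @export
simulate_npx <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  np <- config$npx
  subjects <- subject_table(config)
  assays <- sprintf("P%03d", seq_len(np$n_assays))
  baseline <- seq(np$baseline_range[1], np$baseline_range[2],
                  length.out = np$n_assays)
  cv <- np$cv_floor[["a"]] + np$cv_floor[["b"]] / sqrt(2^baseline)
  sd_log2 <- sqrt(log1p(cv^2)) / log(2)

  eff <- function(compartment) {
    m <- matrix(0, np$n_assays, nrow(subjects),
                dimnames = list(assays, subjects$subject))
    ids <- np$group_assay_ids
    if (length(ids))
      m[ids, ] <- matrix(rep(np$group_effects[subjects$group],
                             each = length(ids)), nrow = length(ids))
    if (compartment == "CSF" && length(np$csf_only_assay_ids)) {
      ids <- np$csf_only_assay_ids
      m[ids, ] <- matrix(rep(np$group_effects[subjects$group],
                             each = length(ids)), nrow = length(ids))
    }
    m
  }
  fixed <- outer(baseline, rep(1, nrow(subjects))) +
    outer(rep(1, np$n_assays),
          np$beta_age * (subjects$age - 45) + np$beta_sex * (subjects$sex == "M"))
  dimnames(fixed) <- list(assays, subjects$subject)

  with_seed(child_seed(config$seed, "npx"), {
    noise <- function() matrix(stats::rnorm(np$n_assays * nrow(subjects),
                                            sd = sd_log2),
                               np$n_assays, nrow(subjects))
    csf <- fixed + eff("CSF") + noise()
    serum <- fixed + eff("Serum") + noise()
    covariates <- data.frame(sample_id = subjects$subject,
                             group = subjects$group, age = subjects$age,
                             sex = subjects$sex, stringsAsFactors = FALSE)
    truth <- list(baseline = stats::setNames(baseline, assays),
                  cv = stats::setNames(cv, assays),
                  group_effects = np$group_effects,
                  group_assay_ids = assays[np$group_assay_ids],
                  csf_only_assay_ids = assays[np$csf_only_assay_ids],
                  beta_age = np$beta_age, beta_sex = np$beta_sex,
                  # mean at which the noise term equals the flat CV floor
                  knee_mu = if (np$cv_floor[["a"]] > 0)
                    (np$cv_floor[["b"]] / np$cv_floor[["a"]])^2 else NA_real_)
    list(csf = csf, serum = serum, covariates = covariates, truth = truth)
  })
}
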