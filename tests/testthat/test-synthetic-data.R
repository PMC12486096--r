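test_that("cohort generation is bit-identical under a fixed seed", {
  cfg <- sim_config(seed = 11, n_genes = 150, n_samples_per_group = 1,
                    n_cells_per_sample = 150)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$cells, b$cells)
  expect_identical(a$counts, b$counts)
  ta <- simulate_tcr(a, sim_config(seed = 11, n_genes = 150,
                                   n_samples_per_group = 1,
                                   n_cells_per_sample = 150,
                                   tcr = list(n_clones = 20L)))
  tb <- simulate_tcr(b, sim_config(seed = 11, n_genes = 150,
                                   n_samples_per_group = 1,
                                   n_cells_per_sample = 150,
                                   tcr = list(n_clones = 20L)))
  expect_identical(ta$contigs, tb$contigs)
  expect_identical(simulate_npx(cfg), simulate_npx(cfg))
})

test_that("null composition effects give equal type proportions across groups", {
  types <- c(CD4_TCM = 0.4, CD8_TEM = 0.3, B_memory = 0.2, Mono = 0.1)
  cfg <- sim_config(groups = c("A", "B"), n_samples_per_group = 3,
                    cell_types = types,
                    composition_effects = matrix(0, 2, 4,
                      dimnames = list(c("A", "B"), names(types))),
                    ifn_effect = c(A = 0, B = 0),
                    n_cells_per_sample = 1000, n_genes = 120, seed = 3)
  co <- simulate_cohort(cfg)
  for (t in names(types)) {
    pa <- mean(co$cells$cluster[co$cells$group == "A"] == t)
    pb <- mean(co$cells$cluster[co$cells$group == "B"] == t)
    se <- sqrt(2 * types[[t]] * (1 - types[[t]]) / 6000)
    expect_lt(abs(pa - pb), 5 * se)
  }
})

test_that("zero interferon effect leaves module-gene expression flat across groups", {
  cfg <- sim_config(groups = c("A", "B"), n_samples_per_group = 2,
                    composition_effects = matrix(0, 2, 8,
                      dimnames = list(c("A", "B"),
                                      names(sim_config()$cell_types))),
                    ifn_effect = c(A = 0, B = 0),
                    n_cells_per_sample = 500, n_genes = 150, seed = 4)
  co <- simulate_cohort(cfg)
  ifn <- co$genes$gene[co$genes$class == "ifn"]
  ma <- mean(as.matrix(co$counts[ifn, co$cells$group == "A"]))
  mb <- mean(as.matrix(co$counts[ifn, co$cells$group == "B"]))
  expect_lt(abs(ma - mb) / ma, 0.05)
})

test_that("contamination spiking matches the closed-form cell count and round-trips", {
  cfg <- sim_config(groups = "G", n_samples_per_group = 1,
                    composition_effects = matrix(0, 1, 8,
                      dimnames = list("G", names(sim_config()$cell_types))),
                    ifn_effect = c(G = 0),
                    n_cells_per_sample = 900, n_genes = 150, seed = 5)
  co <- simulate_cohort(cfg)

  # fraction 0 leaves the cohort untouched
  same <- spike_contamination(co, 0)
  expect_identical(same$cells, co$cells)

  # 900 cells at f = 0.1 without platelets: n/(N+n) = 0.1 gives n = 100
  sp <- spike_contamination(co, 0.1, platelet_ratio = 0)
  per_sample_ery <- table(sp$cells$sample_id[sp$cells$cluster == "Erythrocyte"])
  expect_true(all(per_sample_ery == 100))
  expect_equal(unname(estimate_peripheral_fraction(sp$cells)),
               rep(0.1, 2), tolerance = 1e-12)

  # with co-spiked platelets the requested fraction still round-trips
  sp2 <- spike_contamination(co, 0.08, platelet_ratio = 0.5)
  expect_equal(unname(estimate_peripheral_fraction(sp2$cells)),
               rep(0.08, 2), tolerance = 2 / 900)
  expect_error(spike_contamination(co, 0.9), "too large")
})

test_that("degenerate TCR configs behave as specified", {
  base <- list(groups = "G", n_samples_per_group = 1,
               cell_types = c(CD4_TCM = 1),
               composition_effects = matrix(0, 1, 1,
                                            dimnames = list("G", "CD4_TCM")),
               ifn_effect = c(G = 0), n_cells_per_sample = 50,
               n_genes = 100, seed = 6)
  cfg <- do.call(sim_config, c(base, list(tcr = list(n_clones = 50L))))
  co <- simulate_cohort(cfg)
  sim <- simulate_tcr(co, cfg)
  expect_true(all(sim$truth$size == 1))

  cfg_err <- do.call(sim_config, c(base, list(tcr = list(n_clones = 51L))))
  expect_error(simulate_tcr(co, cfg_err), "more clones than T cells")

  # zero sharing probability plants no cross-compartment clones
  cfg0 <- do.call(sim_config,
                  c(base, list(tcr = list(n_clones = 10L, sharing = 0))))
  sim0 <- simulate_tcr(co, cfg0)
  a <- call_clones(sim0$contigs[sim0$contigs$compartment == "CSF", ])
  b <- call_clones(sim0$contigs[sim0$contigs$compartment == "PBMC", ])
  expect_equal(nrow(trace_clones(a, b)), 0)
})

test_that("clone sizes are distribution-stable under independent re-draws", {
  set.seed(1)
  s1 <- rimflow:::draw_clone_sizes(2000, 300, alpha = 2)
  s2 <- rimflow:::draw_clone_sizes(2000, 300, alpha = 2)
  expect_equal(sum(s1), 2000)
  expect_true(all(s1 >= 1))
  ks <- suppressWarnings(ks.test(s1, s2))
  expect_gt(ks$p.value, 0.001)
  # heavy tail: the largest clone dwarfs the median clone
  expect_gt(max(s1), 10 * stats::median(s1))
})

test_that("NPX generator honors null, noiseless, and compartment-specific settings", {
  # all effects and noise off: both compartments equal the fixed baseline
  cfg0 <- sim_config(seed = 7, npx = list(
    beta_age = 0, beta_sex = 0,
    group_effects = c(noPRL = 0, PRLlow = 0, PRLhigh = 0),
    cv_floor = c(a = 0, b = 0)))
  sim0 <- simulate_npx(cfg0)
  expect_equal(sim0$csf, sim0$serum)
  expect_true(all(abs(sim0$csf - sim0$truth$baseline) < 1e-12))

  # flat CV (b = 0): no noise floor, the filter retains every assay
  cfgf <- sim_config(seed = 8, n_samples_per_group = 10,
                     npx = list(cv_floor = c(a = 0.1, b = 0),
                                group_effects = c(noPRL = 0, PRLlow = 0,
                                                  PRLhigh = 0),
                                beta_age = 0, beta_sex = 0))
  simf <- simulate_npx(cfgf)
  nf <- noise_filter(simf$csf)
  expect_identical(nf$cutoff, -Inf)
  expect_equal(nrow(nf$retained), nrow(simf$csf))

  # CSF-only assays carry the group effect in CSF alone
  cfg <- sim_config(seed = 9, n_samples_per_group = 8)
  sim <- simulate_npx(cfg)
  ids <- sim$truth$csf_only_assay_ids
  hi <- sim$covariates$group == "PRLhigh"
  lo <- sim$covariates$group == "noPRL"
  delta_csf <- mean(sim$csf[ids, hi]) - mean(sim$csf[ids, lo])
  delta_serum <- mean(sim$serum[ids, hi]) - mean(sim$serum[ids, lo])
  expect_equal(delta_csf - delta_serum, 1, tolerance = 0.25)
})

test_that("config validation rejects inconsistent inputs", {
  expect_error(sim_config(cell_types = c(A = 0.5, B = 0.4)), "sum to 1")
  expect_error(sim_config(contamination_fraction = 1), "\\[0, 1\\)")
  expect_error(sim_config(tcr = list(exponent = 1)), "> 1")
  expect_error(sim_config(n_genes = 50), "n_genes too small")
})

test_that("cohort and config survive a YAML round trip and 10x writing", {
  cfg <- sim_config(seed = 12, n_genes = 130, n_samples_per_group = 1,
                    n_cells_per_sample = 80)
  path <- tempfile(fileext = ".yaml")
  write_sim_config(cfg, path)
  cfg2 <- read_sim_config(path)
  expect_equal(cfg2$cell_types, cfg$cell_types)
  expect_equal(cfg2$composition_effects, cfg$composition_effects)
  expect_identical(simulate_cohort(cfg2)$counts, simulate_cohort(cfg)$counts)

  co <- simulate_cohort(cfg)
  dir <- tempfile()
  write_cohort_10x(co, dir)
  back <- read_cohort_10x(dir)
  expect_equal(as.matrix(back$counts), as.matrix(co$counts))
  expect_equal(back$cells$cell_id, co$cells$cell_id)
})
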