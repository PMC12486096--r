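# rimflow

Reusable analysis pipeline for relating cerebrospinal-fluid (CSF) and blood
immune profiles to paramagnetic rim lesion (PRL) burden in multiple
sclerosis. PRL are the MRI correlate of chronic active lesions; cases are
stratified as no-PRL (0 lesions), PRL-low (1–3), and PRL-high (≥4). The
package implements, with tests against planted ground truth, the
computational procedures such a study needs:

- **Staged single-cell QC**: per-sample gene/mitochondrial filters
  (200–5000 genes, <10% mito), pooled mean+2SD / floor filters
  (≥250 genes, ≥500 UMI, ≤2% mito), per-sample doublet-score masking
  (mean+2SD), and single-pass z-score cluster pruning on the embedding;
  log-normalization `ln(1 + 10⁴·count/total)`; cluster-defining genes
  (Wilcoxon, adj p < 0.05, log-scale difference > 0.7, rest detection
  ≤ 30%); pseudobulk aggregation.
- **Peripheral-contribution correction**: per sample, corrected count
  `n_t(1 − p_ery·p_t)` where `p_ery` is the erythrocyte proportion and
  `p_t` the cell-type proportion; erythrocyte/platelet removal.
- **Composition permutation test**: per-cluster log2 fold-difference of
  proportions with a cell-label permutation p-value, bootstrap percentile
  CI, BH-FDR, and the significance rule |log2FD| > 0.41 & FDR < 0.05.
- **Interferon module score**: binned-control average score (24 bins, 100
  controls/gene) of the 14-gene program IFNG, JAK2, IFI6, IFITM2, IFITM3,
  IRF1, IRF7, IRF9, ISG15, MX1, MX2, OAS1, STAT1, IFNGR2.
- **TCR clonality**: clones keyed by identical TRA+TRB CDR3 nucleotide
  sequences (amino-acid mode optional), clonal-space occupancy, the
  high/low-clonal split at clone size ≥ 20, cross-compartment clone
  tracing, and Jaccard repertoire overlap.
- **Olink NPX proteomics**: pairwise cyclic loess normalization with
  negative clamping, a CV-vs-mean noise-floor filter, per-assay ANCOVA
  `NPX ~ group + sex + age` (1.5-fold dialect, 0.58 log2; 1.25-fold,
  0.3219, for ratios), and CSF:serum compartmentalization ratios
  `CSF NPX − serum NPX`; Ella pg/mL preprocessing `log2(raw + 1)`.
- **Cluster transcriptome similarity**: Spearman/Pearson correlation of
  cluster-average profiles against a reference.
- **Synthetic cohort generator**: multinomial cell mixtures with planted
  composition shifts, negative-binomial counts with a planted interferon
  shift, spiked erythrocyte/platelet contamination, power-law TCR
  repertoires with within-subject cross-compartment sharing, and NPX
  matrices with covariate effects, group effects, a CV noise floor, and
  CSF-only analytes — so the whole pipeline is testable end to end with
  known truth.

## Worked example

```r
library(rimflow)

cfg <- sim_config(seed = 42)          # 3 PRL groups, paired CSF/PBMC samples
co  <- simulate_cohort(cfg)
co
#> synthetic_cohort: 600 genes x 10800 cells; 18 samples, 3 groups

qc <- run_qc(co$cells)
qc$stages
#>               stage cells
#> 1             input 10800
#> 2 per_sample_filter 10800
#> 3     merged_filter 10198
#> 4      doublet_mask  9720
#> 5    prune_clusters  9661
```

The staged QC keeps 9661 of 10 800 cells; each row is the survivor count
after that gate. Composition shifts between no-PRL and PRL-high CSF (the
generator plants a 2-fold enrichment of B-memory and Treg cells in
PRL-high):

```r
cells <- co$cells[qc$keep & co$cells$compartment == "CSF", ]
proportion_test(cells, "noPRL", "PRLhigh", seed = 42)
#>    cluster obs_log2FD ci_low ci_high   p_perm    fdr significant
#> 1 B_memory    0.79061  0.469  1.0993 0.000999 0.0040        TRUE
#> 4  CD8_TEM   -0.32367 -0.577 -0.0465 0.012987 0.0346       FALSE
#> 8     Treg    0.71747  0.333  1.1289 0.000999 0.0040        TRUE
#> ...
```

Only the two planted clusters pass the |log2FD| > 0.41 & FDR < 0.05 rule
(CD8-TEM reaches FDR < 0.05 but not the fold threshold — the rule needs
both). The planted log2FD of 1 realizes as ≈0.82 after mixture
renormalization, inside both CIs. The interferon score rises with PRL
burden in blood (the generator plants natural-log shifts 0 / 0.4 / 0.8):

```r
i  <- co$cells$compartment == "PBMC"
sc <- module_score(log_normalize(co$counts[, i]), ifn_signature(), seed = 42)
score_by_group(sc, co$cells$group[i])$summary
#>           group    n    mean  median
#> noPRL     noPRL 1800 -0.0104 -0.0215
#> PRLlow   PRLlow 1800  0.3892  0.3878
#> PRLhigh PRLhigh 1800  0.8043  0.8063
```

The group means recover the planted shifts to within a few percent.
`run_pipeline(cfg, "run_dir")` executes all stages (QC → contamination →
composition → scoring → TCR → proteomics → similarity) for one comparison,
writing per-stage TSVs, a JSON manifest, and a log; reruns are
byte-identical. A thin CLI over the same functions is installed at
`inst/scripts/rimflow` (`rimflow simulate|run|qc|contam|composition|score|
tcr|olink|similarity`).

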