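---
title: "Methods: immune profiling of PRL burden in rimflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: immune profiling of PRL burden in rimflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

rimflow implements, as a tested and reusable pipeline, the computational
procedures used to relate cerebrospinal-fluid (CSF) and blood immune profiles
to paramagnetic rim lesion (PRL) burden in multiple sclerosis: staged
single-cell quality control, erythrocyte/platelet contamination correction of
CSF cell-type counts, a permutation test for cell-composition shifts, a
binned-control interferon module score, paired-chain TCR clonality analysis,
and covariate-adjusted Olink NPX proteomics with CSF:serum
compartmentalization ratios. Because the kind of patient-level data these
methods were designed for is not freely redistributable, the package ships a
synthetic cohort generator with known ground truth; every estimator is tested
by whether it recovers what the generator planted.

This vignette records the models, the tunable parameters, and the places
where a concrete numerical rule had to be chosen.

## Staged single-cell quality control

Cells pass four sequential gates, each seeing only the survivors of the
previous one:

1. **Per-sample filter** — keep cells with 200–5000 genes detected (bounds
   inclusive; whether the published bounds are inclusive is not stated, and
   inclusive was chosen) and mitochondrial percentage strictly below 10%.
   Mitochondrial genes are identified by the `MT-` symbol prefix
   (configurable), since no rule is stated.
2. **Merged filter**, over all samples pooled — drop cells whose gene count
   exceeds the pooled mean + 2 SD or falls below 250; whose UMI total
   exceeds the pooled mean + 2 SD or falls below 500; or whose mitochondrial
   percentage exceeds 2%. The per-sample 10% and pooled 2% mitochondrial
   cutoffs look inconsistent in spirit; they are implemented verbatim as two
   sequential stages.
3. **Doublet mask** — drop cells whose doublet score (an input, not computed
   here) exceeds the mean + 2 SD of scores *within the cell's own sample*.
   A one-cell sample keeps its cell, the SD being undefined.
4. **Cluster pruning** — within each cluster, z-scores of the two embedding
   coordinates are computed separately, and cells with |z| > 3 in either
   dimension are discarded. The threshold is exposed (`prune_z`); exactly one
   pass is applied, so a cell that becomes an outlier only after the gross
   outliers are removed is retained. Clusters with fewer than 3 cells or
   zero coordinate variance are left untouched.

Sample SD (n−1 denominator) is used everywhere, matching the default of the
ecosystem these conventions come from. `run_qc()` records the survivor count
at every stage so drops and survivors always reconcile.

Log-normalization is `ln(1 + 10^4 · count / cell_total)` (natural log).
Cluster-defining genes require adjusted p < 0.05 (two-sided Wilcoxon
rank-sum, Benjamini–Hochberg within cluster — the originating ecosystem's
default test, since none is named), a mean log-scale difference above 0.7
between cluster and rest, and detection in at most 30% of the rest; the
relaxed variant (−0.7 / 40%) used for ontology input is available by passing
a different `marker_rule()`. "Fold difference (log-scale)" is interpreted as
the difference of mean log-normalized expression.

## Contamination correction

The erythrocyte proportion of a CSF sample is taken to represent its
peripheral-blood contribution. For cell type *t* with count *n_t* and
within-sample proportion *p_t*, the corrective factor is
*p_ery · p_t*, and the corrected count is *n_t (1 − p_ery · p_t)*.
Corrected counts are kept as reals (a `round` flag emits integers), because
downstream use is proportions and rounding would break conservation checks.
Platelets are removed along with erythrocytes, but only the erythrocyte
proportion drives the corrective factor. The "cell type proportion within
the same sample" is read as the CSF sample's own proportion, the most direct
reading of an ambiguous phrase.

## Composition permutation test

Per-cluster proportions are compared between two conditions as a log2
fold-difference (log2FD). The null is built by permuting condition labels
over cells (n = 1000 by default), preserving condition sizes; the two-sided
p-value is `(1 + #{|null| ≥ |obs|}) / (n_perm + 1)`. A percentile bootstrap
(cells resampled with replacement within condition, n = 1000) gives the
95% CI, and BH-FDR is applied across the clusters of one comparison only.
A cluster is a significant shift when |log2FD| > 0.41 **and** FDR < 0.05,
both strict.

Numerical choices: clusters absent from one condition receive a 0.5-cell
pseudo-count in both conditions (flagged in the output); the statistic is
computed as a difference of logs and the RNG is consumed in sorted condition
order, so swapping the two conditions negates every estimate bit-exactly and
returns the identical p-value. Cell labels (not sample labels) are permuted,
matching the referenced procedure; a sample-level variant would be the
natural extension but is out of scope here.

## Interferon module score

The 14-gene interferon program (IFNG, JAK2, IFI6, IFITM2, IFITM3, IRF1,
IRF7, IRF9, ISG15, MX1, MX2, OAS1, STAT1, IFNGR2) is scored per cell as the
mean log-normalized expression of the module minus the mean of
expression-matched control genes: genes are ranked by mean expression and
cut into 24 near-equal bins, and up to 100 controls per module gene are
sampled (seeded) from the gene's bin. CSF and PBMC objects are binned and
scored separately.

One deliberate departure from the classic recipe: module genes are excluded
from their own control pool. On full-size expression matrices this is
immaterial, but on matrices of a few hundred genes a coherent module can
fill most of its own bin, and self-sampled controls cancel the very signal
being measured (observed as a five-fold shrinkage of a planted shift). When
a bin holds no non-module genes the scorer warns and falls back to the full
bin.

## TCR clonality

A clone is a set of cells sharing identical CDR3 sequences in both the TCR
α and β chains — nucleotide-level by default, amino-acid level on request
(which provably coarsens the nucleotide partition). V/J identity is *not*
part of the clone key, following the quoted definition; an option could add
it. Within a cell, multiple contigs of one chain resolve to the highest-UMI
contig, ties to the lexicographically smallest sequence; cells lacking
either chain are excluded from paired analyses and reported separately.
Clone ids are FNV-1a content hashes of the key, so identities are stable
across runs. Clonal space occupancy uses half-open relative-proportion bins
(0, 10⁻⁴], (10⁻⁴, 10⁻³], (10⁻³, 0.01], (0.01, 0.1], (0.1, 1] — the published
figures do not print their bin edges — and occupancies sum to 1 by
construction. Cells are "high-clonal" when their clone has ≥ 20 cells,
"low-clonal" below. Cross-compartment tracing intersects clone keys;
repertoire overlap is Jaccard on key sets.

## Olink NPX proteomics

Each comparison's sample subset is normalized by pairwise cyclic loess
(span 0.7, 3 cycles — the originating implementation's defaults), after
which negative entries are clamped to zero. Clamping is applied once, after
the last cycle, and before noise modeling, following the stated order of
operations. Pairwise cyclic loess at 3 cycles is a contraction, not a
projection: a second pass moves entries strictly less than the first, and
is a no-op only at the normalizer's fixed point (already-aligned samples) —
the tests assert exactly that.

**Noise floor.** Per-assay mean and CV are computed on the linear scale
(2^NPX; CV of log-scale values is not meaningful near zero), and CV vs
log2(mean) is lowess-smoothed. The published description — remove assays
below "the lowest mean value at which the linear relationship with CV is
grossly lost" — names no rule, so one had to be made concrete. A
residual-from-a-reference-line rule was tried first and rejected: on a flat
CV profile the upper-half MAD of smoothed residuals collapses to ~10⁻³ and
smoothing wiggle fires the rule, while with an absolute floor added the
reference line (fitted through the genuinely curved upper half) absorbs part
of the rise and the knee is detected a factor of ~2 too low. The shipped
rule works on the same smoothed curve but watches its *local slope*:
scanning from high to low mean, the cutoff is the mean at which the slope
drops below the upper-half median slope by more than max(3 × MAD, 0.02 CV
units per log2 mean). This is exactly null on flat CV and recovers the
generator's planted knee within a factor of 2 on all tested seeds.

**Differential abundance.** Per assay, ordinary least squares of
`NPX ~ group + sex + age`. Two-group contrasts report the group coefficient
(adjusted log2 fold-change) with its t-test p. With more than two groups the
omnibus F p is reported plus a Tukey HSD post-hoc for the requested pair —
computed on the covariate-adjusted values, not on the full model, because
`TukeyHSD` on a model with continuous covariates compares unadjusted group
means against the covariate-reduced error term and measurably inflates
type-I error (0.16 observed under the null, vs 0.04 for the two-step). The
adjusted matrix removes mean-centered age and sex effects and feeds all
downstream analyses. Significance: |adjusted log2FC| > 0.58 (1.5-fold) and
(post-hoc) p < 0.05; the CSF:serum ratio analysis uses the 1.25-fold dialect
(0.3219). BH across assays is applied to the primary p and reported
alongside; post-hoc p-values are left per-assay, both being available to the
reader.

**CSF:serum ratio.** Since NPX is log2-scale, the ratio is the element-wise
difference CSF − serum over assays present in both compartments; sample
columns must align exactly and any mismatch is a hard error. Ella analytes
(pg/mL) are pedestaled (+1) and log2-transformed before entering the same
ANCOVA machinery.

## Cluster transcriptome similarity

Cluster profiles are arithmetic means of log-normalized expression per gene.
Correlation between reference cell types and query clusters is computed over
the intersection of gene symbols (at least 10 required); Spearman is the
headline method, being less sensitive to outliers, with Pearson available.
Both inputs are expected pre-normalized to the same convention.

## The synthetic cohort generator

`sim_config()` / `simulate_cohort()` produce, for each subject, one CSF and
one PBMC sample: cell-type counts multinomial over group-adjusted mixture
proportions (baseline shifted by per-group log2 fold-differences and
renormalized — note the renormalization means a planted log2FD of 1 realizes
as 1 − log2(Z) with Z the normalizing sum); gene counts negative binomial
with shared dispersion; disjoint marker blocks per cell type and for
erythrocytes/platelets, so annotation in fixtures is unambiguous; a
multiplicative per-group shift (natural-log scale, default 0 / 0.4 / 0.8)
on the 14 interferon genes; QC metrics, embeddings, and doublet scores
derived so the QC stage runs unchanged. Defaults (3 subjects per group,
600 cells per sample, 600 genes, baseline mean 1 count, housekeeping and
interferon baseline 20 counts, dispersion 2) were chosen so cells sit
comfortably inside the published QC gates and the interferon genes sit far
from the count floor, where the zero-inflation of the negative binomial
would otherwise bias the recovered shift upward; no published library-size
distribution exists for these data, so these are documented choices, not
estimates. One global seed drives everything; sub-generators derive child
seeds as FNV-1a hashes of a role label folded into the seed, so modules are
independently reproducible.

TCR repertoires draw clone sizes from a truncated discrete power law
(exponent 2 by default): every clone keeps one cell and remaining cells are
allocated multinomially with weights proportional to the raw power-law
draws, which preserves heavy tails while degenerating correctly to all
singletons when clones equal cells. CDR3 nucleotide sequences are random
45-mers over the 61 sense codons (no stops under translation), unique by
rejection; with the sharing probability a blood clone reuses a CSF clone's
key within the same subject. NPX matrices are baseline + age/sex covariate
effects + group effects + lognormal noise whose linear-scale CV follows
a + b/√mean (defaults a = 0.1, b = 0.5); assays carrying the group effect
default to the mid-abundance range, where a differential protein would
actually be quantifiable, and "CSF-only" assays receive the effect in CSF
alone, planting a known compartmentalization contrast. The CV model has no
discontinuity, so the "knee" the noise filter must find is defined as
(b/a)² — the mean at which the noise term equals the flat floor and the CV
doubles.

What the generator does **not** emulate: gene–gene covariance, batch and
ambient-RNA effects, realistic V(D)J recombination, Olink plate effects,
or dropout beyond what the negative binomial implies. Passing tests
therefore demonstrate correctness of the procedures under their own
assumptions, not robustness to every artifact of real data.

## Problem sizes and limitations

The test and acceptance workloads use desk-scale sizes chosen as the
package's own study conditions: cohorts of 6–24 samples at 250–1000 cells
each, 2000 cells per condition for composition power, 1000 permutations and
bootstrap draws, 50-seed recovery loops for ANCOVA and composition power,
20-seed loops for the noise knee, and n = 10 subjects per group for
proteomics. Known limitations: the composition test treats cells as
exchangeable (no within-subject correlation); the contamination correction
acts on composition counts only, not on expression; cyclic loess is
pairwise and O(samples²); and the marker test loops `wilcox.test` per gene,
which is fine at these scales but would want a vectorized rank-sum for
full-size matrices.
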