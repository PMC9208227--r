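---
title: "Methods: somatic-aware cis-eQTL mapping in heterogeneous tumors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: somatic-aware cis-eQTL mapping in heterogeneous tumors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Scope and model

`tumorQTL` maps germline cis-eQTLs in tumor cohorts while explicitly
modelling the two features that distinguish tumors from normal tissue:
somatic perturbation of expression (high-level copy-number alterations,
inactivating point mutations) and cellular heterogeneity (each biopsy mixes
tumor and stromal/immune cells in proportion to its purity).

The mapping model is a two-stage regression. Stage one regresses each gene's
inverse-normal-transformed expression on an intercept, genotype principal
components (ancestry; default 5), hidden expression factors (default 15),
sex, the gene's CNA code (+1 high-level amplification, −1 deep deletion) and
its inactivating-mutation indicator, then re-applies the inverse normal
transform to the residuals. Stage two regresses that vector on each cis
variant's dosage separately. The two-stage form slightly miscounts residual
degrees of freedom relative to a joint fit; this is accepted because
gene-level inference is permutation-calibrated, which absorbs the
approximation.

### Gene-level inference

The minimum nominal p across a gene's cis variants is calibrated by
permuting the phenotype. The scheme is adaptive: after `n_perm_min` (1000)
permutations, a gene stops early if at least 30 permuted minima lie at or
below the observed minimum (the observed statistic is clearly non-extreme);
otherwise it continues to `n_perm_max` (10,000). A Beta(a, b) distribution
is fitted to the permuted minima by maximum likelihood (method-of-moments
start, damped Newton; fallback to the moment estimates with a warning), and
the gene's adjusted p is the Beta CDF at the observed minimum — this
extrapolates below the 1/n_perm resolution of the empirical estimator
`(1 + #exceedances)/(1 + N)`, which is also reported. For k independent null
variants the fitted law approaches Beta(1, k), and the agreement between
beta-approximated and exhaustive empirical p-values is verified in the test
suite (Spearman ρ > 0.99, max |Δ| < 0.02 over the range [0.001, 0.5]).

Storey q-values convert adjusted p-values to gene-level FDR: π₀ is estimated
on the λ grid 0.05…0.95 with a cubic smoothing spline (df = 3) evaluated at
the largest λ and clipped to (0, 1]; families smaller than 100 fall back to
the fixed λ = 0.5 estimator because the smoother is unstable there. Setting
π₀ = 1 recovers Benjamini–Hochberg exactly, which the tests assert. eGenes
are called at q ≤ 0.05, interaction eGenes at q ≤ 0.10 (the interaction
model has intrinsically lower power).

### Interaction model and classification

Interaction eQTLs fit `expression ~ covariates + somatic + genotype + purity
+ genotype×purity` per variant, with purity centered before the product term
so the main and interaction coefficients decorrelate (the interaction
estimate itself is unchanged by centering — an OLS identity asserted
numerically in the tests). The gene-level pass permutes genotype rows
jointly across samples, preserving the purity–expression–covariate
relationship, and reuses the adaptive/beta machinery. Computationally, each
permutation is re-expressed through the inverse permutation applied to the
small fixed design pieces, so batches reduce to a handful of matrix products
against the fixed dosage block.

Significant interaction genes are classified by splitting samples at the 1/3
and 2/3 purity quantiles (linear-interpolation quantiles, boundary ties to
the lower tertile) and regressing covariate-adjusted expression on dosage in
the low and high tertiles separately: `low_purity_only` and
`high_purity_only` when exactly one tertile is significant at α (default
0.05), `opposite_directions` when both are significant with opposite signs,
otherwise `unclassified`. A caveat documented here deliberately: when an
effect scales smoothly with purity (slope ∝ purity) and the cohort is large,
the low-tertile slope is attenuated but not null, so both tertiles can reach
significance and the gene lands in `unclassified` rather than
`high_purity_only`. The one-compartment labels are characteristic of effects
that are weak or absent in the uninformative tertile; the within-tertile α
is configurable for users who want a stricter notion of "absent".

### Somatic associations, variance partitioning, heterogeneity

somQTLs regress transformed expression on covariates plus the somatic codes
and test each somatic coefficient; genes without somatic events are skipped;
Storey q-values run across all tested gene–predictor pairs.

Per-gene expression variance is partitioned by fixed-effect semi-partial R²:
the fraction credited to a predictor group is `(RSS_without − RSS_full)/TSS`
floored at zero, the residual fraction is `RSS_full/TSS`, and the vector is
renormalized to sum to one. For mutually orthogonal groups this equals the
marginal R² decomposition exactly (tested). A mixed-model decomposition with
random effects would shrink the estimates for unbalanced categorical
predictors; the fixed-effect form was chosen for transparency and exact
testability on the balanced synthetic designs used here.

Allelic fold change is estimated on size-factor-normalized, untransformed
expression: covariate effects are removed on the log scale, then expression
is fitted linearly on dosage and `aFC = log2((b0 + 2·b1)/b0)`, clamped to
±log2(100) and undefined when a fitted homozygote expression is
non-positive.

Cancer cell fractions use `CCF = VAF·(p·CNt + (1−p)·CNn)/(p·m)` with
defaults CNt = CNn = 2, m = 1, clamped to [0, 1.5] (values above 1 are
super-clonal artifacts, retained up to the clamp). The MATH heterogeneity
score is the unscaled `MAD(CCF)/median(CCF)` — no 1.4826 consistency
constant and no ×100 — with the conventional scaling available behind
`conventional = TRUE`. Both readings are defensible; the unscaled ratio is
the package default.

## Preprocessing defaults and their rationale

| parameter | default | role |
|---|---|---|
| MAF filter | ≥ 0.01 | drop rare variants with no single-cohort power |
| variant missingness | ≤ 0.95 | permissive by default; tighten to 0.05 for raw array data |
| sample missingness | ≤ 0.025 | drop low-quality genotyping samples |
| imputation r² | ≥ 0.3 | drop poorly imputed variants (when r² present) |
| genotype PCs | 5 | ancestry structure |
| hidden factors | 15 | broad expression variation (PCA stands in for PEER; equivalent role, deterministic, no external dependency) |
| gene filter | ≥ 0.1 TPM and ≥ 6 reads in ≥ 20% samples | remove unexpressed genes |
| outlier cut | 3 SD on first 6 expression PCs | remove aberrant samples |
| cis window | ±1 Mb | standard proximal definition |
| MAC | ≥ 5 | minimum minor-allele observations |
| permutations | 1000–10,000 adaptive | gene-level calibration |
| eGene / ieGene FDR | 0.05 / 0.10 | gene-level significance |
| INT offset | 3/8 (Blom) | rank-to-quantile mapping convention |

The variant-missingness default of 0.95 follows the looser of the two
plausible readings of the upstream QC convention; because it is likely that
a 5% cap is intended in most settings, the threshold is a parameter rather
than a constant. Residual missing dosages are mean-imputed per variant,
which preserves allele frequency and keeps `filter_genotypes` idempotent.
Size factors are the median-of-ratios (geometric mean reference) estimator;
the implementation matches `DESeq2::estimateSizeFactorsForMatrix` to
numerical precision (asserted in a test) and fails loudly when no gene is
positive in all samples rather than silently switching reference. On the
equivariance property: multiplying one sample's counts by c multiplies that
sample's factor by c relative to the others — the geometric-mean reference
itself rescales by c^(1/n), so the invariance is exact on factor ratios.

## The synthetic cohort generator

`simulate_cohort` emulates the structure the pipeline assumes, with a
ground-truth registry for recovery tests.

* **Genotypes.** Genes are tiled at fixed spacing on one synthetic
  chromosome; variant positions are uniform; per-variant MAF is uniform on
  `maf_range`. Haplotypes follow a first-order copying process along the
  chromosome (copy probability 0.9 at zero distance, exponential decay over
  100 kb), giving realistic local LD — the effective number of independent
  tests per cis window, not the raw variant count, is what governs
  multiple-testing burden in real data. Dosages add bounded uniform noise
  (±0.05) to hard calls. Generation fails, naming the deficit, if any gene
  window would hold fewer than 50 variants.
* **Expression.** Latent log expression = baseline + hidden factors
  (variance 0.3) + somatic shifts (±1 SD per event) + cis term; counts are
  negative binomial (dispersion 0.1, the standard bulk RNA-seq observation
  model) around `exp(latent)` with log-normal library sizes (σ = 0.3), so
  size-factor estimation is non-trivial.
* **Cis effects.** A configured fraction of genes receives one causal cis
  variant; the effect is `b·g` (shared), `b·g·purity` (tumor-restricted,
  matching the interaction model's linear functional form) or
  `b·g·(1−purity)` (stroma-restricted). The slope is calibrated per gene so
  the cis term explains `effect_r2` of the observed log-scale expression
  variance — the latent background plus the delta-method count-noise
  variance (dispersion + 1/μ). Calibrating against latent variance alone
  would make realized effects systematically weaker than the configured
  target once counting noise enters.
* **Purity** is Beta(5, 2) truncated to [0.1, 0.99] by default (CPE-like
  spread). The linear purity scaling of compartment-restricted effects is a
  modelling assumption consistent with the interaction model, not an
  empirical claim.
* **Mutations.** Per sample, CCFs are drawn around the configured subclone
  modes (default 1.0/0.6/0.3, sd 0.05, truncated to (0, 1]), converted to
  VAFs through purity and copy number, and observed at binomial read depth
  100. The generated VAFs round-trip through the `ccf()` estimator to the
  drawn CCFs within read-depth noise (tested).

What the generator does **not** emulate: long-range LD and realistic allele
frequency spectra, copy-number variation in mutation loci (CN fixed at 2),
GC/length biases, batch effects beyond hidden factors, multi-cancer-type
structure. Passing recovery tests on these cohorts therefore validates the
statistical machinery, not robustness to every artifact of real TCGA-scale
data.

## Problem sizes used in validation

The validation suite exercises: 50 genes × 10,000 exhaustive permutations
for the beta-approximation oracle; five mixed cohorts of 200 samples × 300
genes (20% true effects at R² = 0.1, ~100 cis variants per gene under a
compact tiling) for FDR/power; 10,000 single-variant null fits for
interaction calibration plus a 300-gene null cohort at the pipeline level;
50 replicates per compartment class (n = 600, high-tertile R² = 0.15, one
causal among 10 cis variants, near-uniform purity on [0.1, 0.99] so the
tertile contrast is informative) for interaction recovery; and a 200 × 200 ×
5000 cohort run twice end-to-end for byte-identical determinism. Interaction
gene passes in these experiments use 250–1000 permutations: the beta
extrapolation resolves gene-level significance well below the empirical
resolution, so the 1000–10,000 pipeline default is not needed for
validation-scale families.

## Numerical and design choices

* PCA signs are fixed (largest-magnitude loading positive) so repeated runs
  are bit-identical.
* Lead variants break p-value ties by genomic position, then id —
  deterministic and invariant to column order.
* Empirical permutation p uses `(1 + x)/(1 + N)`, never zero.
* π₀ is clipped below at 1/m: an exact zero would zero all q-values.
* Per-stage seeds derive from the master seed by mixing it with the stage
  name (`stage_seed`), so any stage can be rerun in isolation.
* The interaction design matrix drops constant somatic columns and fails
  with the offending column names on rank deficiency; constant purity is an
  explicit error.
* `effect_class_probs` defaults to 70% shared / 20% tumor-restricted / 10%
  stroma-restricted: most regulatory variation is expected to be shared
  across compartments, with tumor-restricted effects more common than
  stroma-restricted ones in high-purity cohorts.
* Mutation multiplicity defaults to 1 and tumor copy number to 2 when
  absent; the CCF estimator is the exact inverse of the generator's VAF
  model, which the round-trip test exploits.

## Known limitations

* Hidden-factor estimation by PCA can absorb a small share of strong genetic
  signal in small gene panels; on genome-scale panels this is negligible.
  Validation runs estimate as many factors as were simulated.
* The classification caveat above: smoothly purity-scaled effects in large
  cohorts tend to `unclassified` rather than a one-compartment label at the
  default within-tertile α.
* somQTL p-values are t-tests, not permutation-calibrated (only the
  multiple-testing treatment mirrors the eQTL side).
* No trans-eQTLs, conditional secondary signals, fine-mapping, phasing or
  imputation; purity is an input, never inferred.
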