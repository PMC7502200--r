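---
title: "Measuring inter-individual expression variability across embryogenesis"
author: "devnoise"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring inter-individual expression variability across embryogenesis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Isogenic embryos reared in a common environment still differ in how much of
each transcript they express. This inter-individual *expression
variability* (expression noise at the whole-organism scale) is
biologically structured: it changes over developmental time, and the
evo-devo hourglass model predicts it should be lowest at the
phylotypic stage — mid-embryogenesis, when body-plan patterning is most
constrained. Testing that prediction from replicate single-embryo RNA-seq
requires (i) a variability metric that is not confounded by expression
level, (ii) careful preprocessing of shallow 3'-end count data, and
(iii) ways of relating per-gene variability to regulatory features:
promoter sequence conservation and promoter histone-modification signal.

devnoise implements that full pipeline, together with a seeded
synthetic-data generator whose ground truth makes every stage of the
pipeline testable by parameter recovery.

## Variability metrics

Let $e_{gj}$ be log2-scale expression of gene $g$ in embryo $j$, and let
stages partition the embryos. All standard deviations below are
population SDs (divisor $n$); this convention is fixed and used
consistently, so only ratios of SDs matter downstream.

**CV.** $\mathrm{CV}_{gs} = \mathrm{SD}_{gs} / \mathrm{mean}_{gs}$. On
count-derived data the CV falls steeply with expression level, making
cross-gene and cross-stage comparisons unreliable.

**Distance to median (DM).** Genes are ordered by global mean
expression and tiled into sliding windows of 50 genes with 25 genes of
overlap. A gene's DM at stage $s$ is its stage-specific
$\log_{10}\mathrm{CV}^2$ minus the median *global* $\log_{10}\mathrm{CV}^2$
of its window. Each gene is assigned to the window whose centre gene (the
$\lceil w/2\rceil$-th member) is nearest its rank; ties go to the lower
window. Genes with zero global CV are excluded before ranking.

**Adjusted SD.** A polynomial (OLS) trend predicts each gene's *global*
SD from its *global* mean. The degree grows from 1 while the nested-model
F-test against the previous degree improves the fit at $p < 0.05$; if
even degree 1 is no improvement, the intercept-only model is kept.
The adjusted SD of gene $g$ at stage $s$ is then

$$\mathrm{adjSD}_{gs} = \frac{\mathrm{SD}_{gs}}{\max(\hat f(\bar e_g),\ \varepsilon)},
\qquad \varepsilon = 10^{-6},$$

the observed stage SD over the trend-predicted global SD. Because the
denominator absorbs the mean–SD relationship, adjusted SD is
mean-independent by construction; on a null simulation (all stages
identically distributed, 5,000 genes) its Spearman correlation with mean
expression is below 0.05 in absolute value while CV's exceeds 0.85 on the
same matrix. The trend is fitted once on the full data; bootstrap and
subsampling analyses reuse it (refitting per replicate is available via
`refit_trend`), since the predicted *global* SD is a property of the full
data set.

## Preprocessing

- **Sample QC**: samples with fewer than 0.3 million total counts or
  fewer than 4,500 expressed genes (count ≥ 1) are removed; both
  thresholds are inclusive (removal is by strict `<`).
- **Gene filter**: genes with mean cpm across samples ≤ 1 are removed;
  retained genes keep their original integer counts.
- **Normalization**: `log2(cpm + 0.5)` followed by full quantile
  normalization across samples (limma). The default tie handling
  (`ties = "first"`) assigns tied entries distinct ranks
  deterministically, so every column ends with the *identical multiset*
  of values — exactly. `ties = "average"` gives tied entries the mean of
  the values they would have received (the limma convention) at the cost
  of exact multiset equality; the two differ only at tied values.
- **Batch correction**: parametric empirical-Bayes location/scale
  adjustment (ComBat) across library batches, protecting stage as a model
  covariate by default so stage signal partially aligned with library is
  not erased (`protect_stage = FALSE` disables this). Afterwards the
  matrix is clipped: negative corrected values, and entries whose
  pre-correction value was exactly 0, become 0 — so the expression matrix
  used by all downstream weighted analyses is non-negative and zeros are
  preserved.
- **MDS**: classical principal-coordinates embedding of
  $d(i,j) = 1 - r_{ij}$ (Pearson correlation of expression columns), with
  axis signs standardized for determinism.
- **Arrested-sample flagging**: unfertilized eggs complete meiosis, then
  arrest; they form a stage-unstructured cluster. The samples are split
  by 2-means on the MDS embedding (initialized at the two most distant
  samples, hence deterministic) and the cluster whose mean correlation
  with an arrested-egg reference profile exceeds the other's by at least
  `min_cor_gap = 0.1` is flagged. The gap requirement is what makes the
  null case (no arrested samples) produce no flags: with a plain
  "higher mean wins" rule one cluster always wins. A meiosis-gene
  enrichment score (mean within-sample expression rank of meiosis genes
  minus the mean rank of all genes) is reported per sample as supporting
  evidence.

## Stage comparisons and robustness

Per-stage medians of a metric are compared by all pairwise two-sided
Wilcoxon rank-sum tests with Benjamini–Hochberg correction over the set
of pairs. Two resampling analyses probe robustness:

- `bootstrap_stage_medians()` resamples a common $n$ (the smallest stage
  size) of samples with replacement within each stage, recomputes
  adjusted SD against the fixed global trend, and keeps the median across
  genes — 500 medians per stage by default, compared again by Wilcoxon.
  One caveat is worth stating plainly: this Wilcoxon is *descriptive*,
  not calibrated. The bootstrap medians concentrate around the realized
  stage medians, so the test has power against the finite-sample
  difference between the observed stages even when the underlying
  distributions are identical, and its rejection rate grows with the
  number of bootstrap replicates. It usefully ranks and separates stages
  whose noise levels genuinely differ; it is not a null-calibrated
  hypothesis test.
- `subsample_equal()` draws the same number of embryos per stage
  *without* replacement (default 8 × 500 repetitions) and records the
  stage medians, showing that stage differences are not an artifact of
  unequal stage sizes.

Gene-set re-analyses (`group_compare`, and the `genes =` argument of
`stage_summary`) support the standard controls: essential genes and
protein-interaction hubs versus the rest, excluding maternally deposited
genes, and restricting to genes expressed at every stage.

## Stage-specific genes and the hourglass profile

A gene's 8-value per-stage mean-expression vector is correlated
(Pearson) with each one-hot stage template; per template, the top 10% of
eligible genes (floor rule, ties broken by gene id) form that stage's
specific set. Per-stage aggregation uses the mean, because the template
has one entry per stage. Constant genes have undefined correlations and
are excluded with a note. A gene may fall into several sets; the overlap
is reported, not resolved. `hourglass_genes()` applies the same template
logic to adjusted-SD profiles against the across-gene median profile.

## Promoter conservation and the TPI

The core promoter is the experimentally validated −49..+10 window around
the representative TSS — 60 bp including the TSS base, mirrored on the
minus strand; 200 bp, 400 bp and 1 kb windows centred on the TSS are
available for sensitivity analyses. Mean conservation over a region is
the unweighted per-base mean; uncovered bases are excluded from numerator
and denominator, and the uncovered fraction is reported.

The transcriptome index of promoter conservation is the
expression-weighted mean score per stage:

$$\mathrm{TPI}_s = \frac{\sum_i \mathrm{phastCons}_i\, e_{is}}{\sum_i e_{is}},$$

with $e_{is}$ the per-stage mean of the non-negative log-scale expression
(which is why the clipping rule above matters). Confidence intervals come
from resampling gene ids with replacement (default 10,000 times) and
taking the empirical 2.5%/97.5% percentiles. Percentile intervals for
ratio estimators undercover slightly at small gene counts: in repeated
synthetic experiments with 200 genes the 95% interval covers the
population TPI about 93–95% of the time, approaching nominal coverage as
the gene count grows.

## Histone signal

Signal tracks are background-subtracted tag densities in fixed 35-bp
windows. A gene's promoter signal is the unweighted mean score of all
windows overlapping the proximal promoter (TSS ± 2 kb) — interval-map
"mean" semantics, so a window counts once regardless of overlap length
(up to 34 bp of slop per side). To compare signal across stages and
libraries, each track is standardized against its own intergenic
background: $\mu$ and $\sigma$ are computed over windows *fully
contained* in the intergenic regions (the genome minus all proximal
promoters and gene bodies, merged before complementing; windows
straddling a boundary are excluded and counted), and every window maps to
$(x-\mu)/\sigma$. The transform is affine, so rank-based analyses are
unchanged by it — a property the tests verify exactly.

Spearman correlations relate per-gene across-stage mean signal to
across-stage mean variability and to promoter conservation;
`partial_spearman()` computes the first-order partial correlation on
ranks (the standard formula $r_{xy\cdot z}$) to control for promoter
shape, and is tested against an independent residual-regression oracle.

## The synthetic-data generator

`simulate_counts()` draws, for fertilized embryo $j$ at stage $s$,
$\mathrm{NB}(\mu = L_j p_{gjs},\ \phi)$ counts, where $p_{gjs}$ is the
normalized expression fraction of a per-embryo perturbed mean
$\mu_{gs}\exp(\varepsilon_{gj}) b_{g,\mathrm{batch}(j)}$ with
$\varepsilon_{gj} \sim N(0, (\sigma_g k_s)^2)$. The pieces, and what they
emulate:

- **Stage trajectories** $\mu_{gs}$: smooth per-gene curves (linear
  drift + one Gaussian bump, amplitudes scaled by `stage_effect_sd`,
  default 0.7), plus an exponential decay component for maternal genes
  (default 50% of genes) that dominates the earliest stage — so MDS
  recovers an ordered trajectory and early samples are maternal-like.
  Setting `stage_effect_sd = 0` with no maternal genes gives exactly
  identically distributed stages (the null configuration).
- **Stage noise multipliers** $k_s$: the default
  $(1.6, 1.3, 1.0, 1.05, 1.2, 1.1, 1.3, 1.5)$ is hourglass-shaped with
  its minimum at stage 3, the phylotypic-like stage.
- **Gene noise scale** $\sigma_g$: log-normal (median 0.35, log-SD 0.5)
  times $(\mu_g/\tilde\mu)^{-0.27}$ — lowly expressed genes are noisier,
  as consistently observed in expression-noise data. With this scaling
  the mean–SD trend is smooth and biology-dominated across the
  expression range, which is the regime in which a polynomial trend can
  remove the mean dependence. Essential genes and hubs get their
  $\sigma_g$ multiplied by 0.7 (their lower variability is a positive
  control).
- **Technical noise**: NB dispersion $\phi = 0.01$ models residual
  library-preparation overdispersion beyond Poisson counting (BCV ≈ 0.1).
  Embryo-to-embryo biology is carried entirely by the log-normal factor;
  putting biological-replicate-level dispersion into $\phi$ as well would
  double-count it.
- **Batches**: 4 libraries with per-gene log-normal batch factors
  (log-SD 0.1), assigned balanced across samples.
- **Arrested samples**: with probability `unfertilized_fraction` a
  sample draws from one stage-independent profile — the stage-1 profile
  diverged by a per-gene log-normal factor (log-SD 1.2) with
  meiosis-related genes up 4-fold — regardless of its nominal collection
  stage. The divergence reflects that an arrested egg is not equivalent
  to any fertilized stage; it is also what makes the arrested cluster
  geometrically separable in MDS, as in the real data.
- **Genome** (`simulate_genome()`): genes laid end-to-end on six fly-like
  chromosome arms with one representative TSS each; per-base conservation
  covering TSS ± 2.5 kb (inner ±500 bp at the gene's conservation level,
  flanks at background 0.1, uncovered elsewhere); 35-bp signal tracks
  tiling each chromosome with exponential background and promoter windows
  at the gene's stage-modulated histone level. Promoter conservation and
  histone level are tied to $\sigma_g$ through a Gaussian copula hitting
  the configured Spearman targets (defaults −0.3 and −0.4) within ±0.05;
  the stage modulation of signal is inverse to $k_s$, so the quietest
  stage carries the strongest promoter marks. Conservation values are
  rounded to 4 decimals and signal to 3, so every track round-trips
  bit-identically through the plain-text writers and readers.

What the generator does **not** emulate: read-level artifacts
(alignment, UMI chemistry, 3'-bias), sequence-level promoter structure,
correlated gene programs (genes are conditionally independent given
stage), chromosome-level effects such as dosage compensation, and any
cross-species divergence. Passing recovery tests on this generator shows
the estimators measure what they claim under a realistic noise model —
not that every biological claim would survive those unmodeled features.

## Numerical and design choices

- Population SD (divisor $n$) everywhere; documented, fixed.
- Trend predictions floored at $10^{-6}$ before division.
- DM window centre = the $\lceil w/2\rceil$-th member; nearest-centre
  assignment, ties to the lower window; stage entries with zero CV are NA.
- Quantile-normalization ties: `"first"` by default (exact multiset
  equality), `"average"` for limma compatibility.
- Top-fraction selections use the floor rule with ties broken by gene id,
  so set sizes and membership are deterministic.
- 2-means for flagging is initialized at the two most distant samples in
  the embedding — no random restarts, fully reproducible.
- Every stochastic routine takes an explicit seed and restores the
  caller's RNG state; the pipeline fans one master seed out to per-stage
  child seeds by hashing stable stage labels, so adding a stage never
  shifts another stage's stream.

## Problem sizes used by the test suite

The suite runs the full design (5,000 genes, 8 × 18 embryos) for the
mean-independence, hourglass-recovery (20 seeds), coupling-recovery and
flagging checks; oracle-equivalence checks use 200-gene / 200-case
instances at tolerances of $10^{-10}$ (DM) and $10^{-6}$ (partial
Spearman); the TPI coverage experiment uses 200 replications of 200
genes with 2,000 bootstrap resamples. Shared fixtures are built once per
session at 2,000 genes × 12 embryos.

## Limitations

- The bootstrap stage comparison is descriptive (see above).
- The percentile TPI interval undercovers by ~1–2 points at 200 genes.
- The copula construction couples both regulatory features to the same
  latent noise scale; their mutual correlation is therefore positive by
  construction, and analyses of the signal–conservation relationship on
  synthetic data inherit that sign.
- `flag_unfertilized` assumes the arrested cluster is geometrically
  separable in the embedding; heavily confounded designs would need the
  reference-correlation threshold instead.
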