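---
title: "Methods: cross-study meta-analysis and network inference in stressnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-study meta-analysis and network inference in stressnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stressnet)
```

# Overview

`stressnet` answers a compendium-scale question: across many small,
independent two-group expression studies spanning several nutrient
stress types, which genes respond under two or more stresses, how do
those genes relate to genotype-specific gene sets, and which
transcription factors sit at the center of the induced networks? This
vignette is the package's own account of the statistical machinery,
the defaults, and the choices made where the design was genuinely open.

# Per-study model

Each study is a two-group comparison on the log2 intensity scale. For
gene $g$, the effect is the difference of group means
($\log_2\mathrm{FC}$), the residual variance $s_g^2$ is the pooled
within-group variance with $d = n_1 + n_2 - 2$ degrees of freedom, and
groups of fewer than two samples are rejected (the within-group
variance is undefined). The pooled (not Welch) form matches the linear
two-group model; multi-factor designs are out of scope.

Gene-wise variances with $d = 4$ are noisy, so they are shrunk by
empirical Bayes toward a prior $s_0^2$ with $d_0$ prior degrees of
freedom. Assuming $s_g^2 \sim s_0^2 F(d, d_0)$, $\log s_g^2$ has a
known mean and variance in terms of digamma/trigamma functions;
`estimate_moderation()` solves the trigamma equation by Newton
iteration (moment matching on the log variances). When the observed
spread of $\log s_g^2$ does not exceed the spread expected under a
single shared variance, $d_0 = \infty$ and $s_0^2$ is the
digamma-corrected geometric mean. The moderated statistic

$$\tilde t_g = \frac{\log_2\mathrm{FC}_g}
{\sqrt{\tilde s_g^2 (1/n_1 + 1/n_2)}}, \qquad
\tilde s_g^2 = \frac{d_0 s_0^2 + d s_g^2}{d_0 + d}$$

is referred to a $t$ distribution on $d_0 + d$ df (standard normal when
$d_0 = \infty$). $d_0 = 0$ recovers the ordinary pooled $t$; genes with
zero sample variance are handled automatically because
$\tilde s_g^2 \ge d_0 s_0^2 / (d_0 + d) > 0$. The test suite
cross-checks the whole route — hyperparameters and moderated p-values —
against the reference empirical-Bayes implementation in `limma`, which
is never used as the implementation itself.

DEGs are called at $|\log_2\mathrm{FC}| > 1$ (strict) and BH-adjusted
$p < 0.05$, the conventional microarray gates; both are arguments
everywhere they appear.

# Cross-study combination

Within each stress type, per-study evidence is pooled by the
inverse-normal (Stouffer) method on directional one-sided p-values:
$z_i = \mathrm{sign}_i \, \Phi^{-1}(1 - p_i/2)$ and
$Z = \sum_i w_i z_i / \sqrt{\sum_i w_i^2}$ with $w_i = \sqrt{n_i}$.
The square-root-sample-size weights are the standard choice and are
robust to scale differences across platforms; inverse-variance
effect-size pooling (`combine_effect_sizes()`) is provided for parity
behind its own function. One-sided p-values of exactly 0 or 1 are
clamped to $[10^{-300}, 1 - 10^{-16}]$ with a warning. Direction
conflicts are not filtered — opposite signs cancel in $Z$ — and a
per-gene direction-consistency score is reported for diagnostics.
Random-effects pooling and heterogeneity statistics are out of scope.

**Common-responsive calling.** A gene is common stress-responsive when
its combined p passes the 0.05 gate in at least two stress types. The
gate is applied to *BH-adjusted* combined p-values by default
(`adjust = TRUE`). This follows the default behavior of the standard
inverse-normal meta-analysis workflow, which reports FDR-adjusted
combined p-values, and it is the calibrated choice: with three stress
types and thousands of genes, a raw 0.05 gate admits roughly
$3 \times 0.05^2$ of all null genes plus every strongly single-stress
gene that clears 0.05 once by chance, which overwhelms a planted
common set of a few dozen genes (measured on the generator's standard
conditions: planted-truth FDR of 0.5–0.7 raw versus 0–0.03 adjusted,
with sensitivity 1 either way). The raw gate remains available via
`adjust = FALSE`. The fold-change gate is *not* re-applied after
combination; membership is defined by the combined evidence alone.

# Normalization

`quantile_normalize()` forces every sample to share the identical value
distribution (rank-wise across-sample means; ties share the midrank
mean). It is exposed for inputs that need it, but `run_pipeline()`
defaults to `normalize = FALSE`: the pipeline's canonical inputs are
already-normalized log2 matrices — platform-level normalization (RMA or
equivalent) happens upstream of this package — and re-normalizing a
small compendium whose columns already share a common scale only
injects rank noise, which the meta stage then amplifies into
stress-consistent artifacts. Probe-to-locus collapsing discards
unmapped and ambiguous probes and averages multiple probes per locus
(per-sample arithmetic mean — symmetric and order-independent; a
`max_intensity` rule is available). Collapsing happens before DEG
calling. Background correction and missing-value imputation are out of
scope.

# Set statistics

The overlapping coefficient $|A \cap B| / \min(|A|, |B|)$ ranges from 1
(nested) to 0 (disjoint). Enrichment uses the upper-tail hypergeometric
probability $P(X \ge |A \cap B|)$, the standard convention including
the observed count. The universe is an explicit argument and is always
reported: overlap p-values are meaningless without it, and for real
compendia the honest default is the set of genes surviving
preprocessing. Venn partitions for two or three sets complete the
module.

# Profile clustering and PCA

Common-responsive genes are clustered on their genes × stress-types
matrix of cross-study mean $\log_2$FC (the profile most comparable
across stresses). k-means uses Lloyd's algorithm with k-means++
initialization, the best of `n_init = 25` restarts by total
within-cluster SS, Euclidean distance without row standardization
(profiles already share the log2FC scale; `standardize = TRUE`
z-scores rows), and $k = 5$ as the default grouping. The Lloyd loop is
implemented in the package because three details are pinned that a
generic implementation does not expose: the within-run monotonicity of
the objective is asserted at every iteration, empty clusters are
re-seeded from the point farthest from its assigned centroid, and
clusters are relabeled G1..Gk by decreasing size for stable reporting.
`stats::kmeans` serves as an independent cross-check in the tests. PCA
is column-mean-centered SVD via `prcomp`; a constant matrix is flagged
degenerate rather than erroring.

# Co-expression network

All-pairs Pearson correlations across the assembled compendium's
samples (computed jointly over all studies) are converted to p-values
by $t = r\sqrt{(n-2)/(1-r^2)}$ on $n - 2$ df, two-sided, then adjusted
by BH across all pairs within the network's gene set (Bonferroni
available). Edges with adjusted $p < 5\times10^{-4}$ are kept with the
signed correlation as weight — co-repression is retained, not only
positive co-expression. Zero-variance genes are excluded with a
warning. Hubs are ranked by degree with lexicographic tie-breaking.
Soft-thresholding, topological overlap, and module eigengenes are
deliberately out of scope: edge-significance filtering is the part of
that toolbox this pipeline uses.

# Directed network inference

For each target gene, an ensemble of `n_trees = 1000` regression trees
predicts the target from TF expression (a TF never predicts itself).
At each split, `ceiling(sqrt(#TFs))` candidate regulators are drawn —
uniformly, or with probability proportional to a nonnegative prior
weight matrix (TF-binding conservation, functional association, or any
other evidence); uniform priors recover plain ensemble inference, so a
single implementation covers both the unsupervised and the
prior-guided variant, which differ only in the sampling distribution.
Edge importance is the total variance (impurity) reduction per TF,
normalized per target to sum to 1. Trees are grown to `min.node.size =
2` with unlimited depth; all hyperparameters are arguments. The tree
ensembles are fitted by `ranger` (single-threaded, seeded), with the
prior-weighted candidate sampling mapped onto its weighted
split-variable selection; the per-target orchestration, normalization,
and scoring are the package's own. The determinism contract is:
identical seed and identical input ordering give identical scores;
refitting on permuted samples is statistically indistinguishable but
not bit-identical. Thresholding keeps the `top_n` highest-scoring
edges (ties broken by TF/target order) or applies a score cutoff —
exactly one selector, since the field reports no canonical cutoff.

# The synthetic-data generator

`simulate_multistudy()` emulates the structure of a multi-study
compendium: several stress types, several independent studies per
stress, a control and a treatment group of a few replicates each, and
independent Gaussian noise on the log2 scale (matching the analysis
assumptions for RMA-style processed intensities). A per-gene baseline
is drawn once and shared across all studies, creating realistic
cross-study correlation. True responders add a per-(gene, stress)
signed effect whose sign is fixed across studies of that stress, so
directional combination is coherent; the common pool responds in a
random subset of ≥ 2 stress types. Two genotype-specific sets are
planted with exact intersections with the common pool. The regulatory
layer draws TF expression as standard normal and each target as a
weighted sum of its true parents plus noise, with a prior matrix
placing `prior_accuracy` of its mass on true edges.

Defaults — chosen once as the study conditions, not tuned: 2000 genes;
3 stress types; 4 studies per stress; n = 3 per group (a typical
replicate count for public two-group microarray studies); 5% of genes
responsive per stress with 30% of them from the common pool; effect
$|\log_2\mathrm{FC}| \sim |N(2, 0.5)|$ with random sign; residual sd
0.25 (log2 scale); genotype sets of 150 and 120 genes with planted
intersections 15 and 25 (a scaled-down analogue of compendium-scale
set sizes); 20 TFs × 5 targets each over 60 samples, coupling
coefficients of magnitude 0.5–1.5 and target noise sd 0.5; prior
accuracy 0.8. A single master seed derives per-study substreams, so
identical seeds give bit-identical output.

What the generator does **not** emulate — and what passing tests
therefore do not show about real data: probe-level effects, batch and
platform differences, correlated (non-diagonal) noise, heavy-tailed
intensity distributions, count-based RNA-seq error, and biological
direction heterogeneity across studies of one stress. Recovery that is
near-perfect here bounds implementation correctness, not real-data
power.

# Numerical choices and degenerate inputs

One-sided p clamping to $[10^{-300}, 1 - 10^{-16}]$; trigamma-inverse
Newton iteration to relative tolerance $10^{-10}$; k-means ties in
assignment broken by first index, label ties by original order;
correlation $|r| = 1$ mapped to $p = 0$ (always retained); PCA of a
constant matrix flagged degenerate; empty gene sets are errors for the
overlapping coefficient (undefined ratio) but produce $p = 1$ for
disjoint overlaps; probe collapsing with an empty surviving set is an
explicit error.

# Problem sizes in the test suite

The suite exercises the pipeline at desk scale, chosen so the full run
completes in a few minutes: null calibration on 10,000 genes,
hyperparameter recovery on 20,000 simulated variances, the standard
2000-gene compendium for end-to-end recovery, 100 replicates of
200-gene null co-expression, and ten seeds of the 20-TF/100-target
regulatory benchmark at 1000 trees. Exhaustive enumeration oracles
(step-up FDR, hypergeometric tails for universes up to 12) guard the
exact statistics.

# Known limitations

Two-group contrasts only (no covariates, pairing, or time-course
modeling); fixed-effect combination (no heterogeneity modeling); the
hypergeometric test assumes a well-defined exchangeable universe;
k-means assumes roughly spherical profile groups on the log2FC scale;
random-forest importances are biased toward high-variance regulators
when sample sizes are very small (a warning fires below 10 samples);
and the prior matrix is taken at face value — no calibration of prior
quality is attempted beyond the planted-accuracy benchmark.
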