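---
title: "Detecting temporal expression-pattern shifts: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting temporal expression-pattern shifts: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A two-condition time-course RNA-seq experiment (for example control versus
treated tissue sampled at 0, 12, 24, 48 and 72 h with three biological
replicates) asks a question that point-wise differential expression does not
answer: *which genes change their temporal expression pattern between the
two conditions?* A gene may be unexpressed under control and rise sharply
after treatment, switch off under treatment, or exchange one dynamic shape
for another while its average abundance barely moves.

`trajshift` answers this with a cluster-then-compare design. Every
per-replicate expression trajectory — one gene, one condition, one
replicate, a vector over the ordered time grid — is clustered into a shared
label space; a gene's per-condition label is then the *consensus* of its
replicates, and a gene whose consensus labels differ between conditions is
a shift gene. Replicates are never averaged: averaging discordant
replicates fabricates trajectories nobody measured, while consensus
labelling simply abstains when replicates disagree.

## The pipeline

1. **Input and normalization** (`read_gem`, `quantile_normalize`,
   `log_transform`). The input is a genes x samples FPKM matrix; sample
   names (or a sample sheet) carry condition, time and replicate. Columns
   are quantile-normalized to the per-rank across-sample means (ties get
   the mean of their tied ranks) and transformed to log2(x + 1).
2. **Off-gene extraction** (`extract_off_genes`). A gene is *off* under a
   condition when at least `min_zero_replicates` (default 1) of its
   replicates are exactly 0 FPKM at every time point. This runs on the raw
   FPKM matrix *before* normalization, because normalization destroys
   exact zeros. Off gene-conditions are never clustered; their label is
   `OFF` by construction.
3. **Initial clustering** (`sdtw_kmeans`). All remaining trajectories,
   pooled over both conditions and all replicates, are partitioned by
   K-means under the soft dynamic-time-warping loss
   $\mathrm{sdtw}_\gamma(x,y) = -\gamma \log \sum_{\pi}
   e^{-\mathrm{cost}(\pi)/\gamma}$, the sum running over all monotone
   alignment paths with squared-difference ground cost. Pooling both
   conditions is essential: the shift comparison is only defined if
   control and treated labels live in one label space.
4. **k selection** (`evaluate_k_grid`, `select_k`). The grid of candidate
   k is scored with the Davies-Bouldin index (lower better), the
   Calinski-Harabasz index (higher better) and the silhouette (higher
   better), computed on the trajectories as fixed-length Euclidean
   vectors. The three rankings are combined by mean rank; ties go to the
   smallest k. No single accepted rule combines these indices, so the
   consensus rule is recorded in the k-selection report.
5. **DP-GP refinement** (`dpgp_cluster`). Each initial cluster is
   re-clustered with a Dirichlet-process mixture of Gaussian processes:
   each sub-cluster has a latent smooth mean drawn from a zero-mean GP
   with squared-exponential kernel
   $k(t_i,t_j) = \sigma_f^2 e^{-(t_i-t_j)^2/2\ell^2}$, and members observe
   it with independent Gaussian noise $\sigma_n^2$. A collapsed Gibbs
   sampler under a Chinese-restaurant-process prior (concentration
   $\alpha$, default 1) reassigns each trajectory with probability
   proportional to cluster size times the marginal-likelihood ratio, or
   $\alpha$ times the singleton marginal for a new sub-cluster. The latent
   mean is integrated analytically (Woodbury identity), so each move costs
   $O(T^2)$ after an $O(T^3)$ precomputation per cluster size. Post
   burn-in partitions accumulate a co-clustering similarity matrix, and
   the returned partition is the sampled one closest (least squares) to
   that matrix. The composite label `K{initial}_D{fine}` is the final
   trajectory label.
6. **Validation** (`validate_with_classifier`). Classes with fewer than
   two members are excluded, the rest are split 70/30 stratified, and a
   sequence classifier (default: 1-nearest-neighbour under soft-DTW)
   predicts the hold-out labels; the confusion matrix and support-weighted
   F1 quantify how learnable the final labels are from the series alone.
7. **Replicate sorting and shift calls** (`sort_replicates`,
   `classify_shift`, `compile_shift_table`). Per gene and condition, the
   label shared by at least `min_agree` of the m replicates (min_agree
   must exceed m/2, so the consensus is unique; 2 or 3 for triplicates) is
   the consensus, otherwise the gene-condition is `UNQUALIFIED`.
   Categories: off to dynamic (A), dynamic to off (B), dynamic to a
   different dynamic label (C), identical labels (non-shift), off in both
   (excluded from shift statistics), any unqualified side (unqualified).
   The identities shift = A + B + C and qualified = shift + non-shift hold
   by construction.
8. **Trajectory sets and enrichment** (`group_trajectory_sets`,
   `enrich_sets`). Qualified genes sharing a (control label, treated
   label) signature form a trajectory set, named by descending size.
   Each set is tested per annotation term with the one-sided Fisher
   (hypergeometric upper-tail) test against the background of all genes
   in the matrix, with Benjamini-Hochberg correction applied within each
   vocabulary and significance declared at adjusted p < 0.001. Singleton
   sets are not tested.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `gamma` | 1.0 | soft-DTW smoothing; smaller values approach classic DTW |
| `k_grid` | 35:90 step 5 | candidate initial k; suited to organism-scale matrices — use a grid bracketing the expected pattern count for small inputs |
| `n_init` | 5 | k-means restarts (distance-weighted seeding) |
| `min_agree` | 3 | replicates that must share a label (2 or 3 for m = 3) |
| `dpgp_alpha` | 1.0 | CRP concentration; larger favours more sub-clusters |
| `dpgp_max_iter` | 1000 | Gibbs sweeps per refined cluster |
| `burn_frac` | 0.5 | fraction of sweeps discarded before accumulating the similarity matrix |
| `min_zero_replicates` | 1 | all-zero replicates needed to call a gene off |
| `enrich_alpha` | 0.001 | adjusted-p threshold for enrichment |

GP hyperparameters default to empirical-Bayes rules
(`estimate_hyperparams`): signal variance = pooled sample variance, noise
variance = a quarter of it, length scale = half the time span, all floored
away from zero. Inside `run_pipeline` the noise variance is instead
estimated from the data's replicate structure: the across-replicate
variance per (gene, condition) and time point, median-pooled
(`replicate_noise_var`). Biological replicates are a direct measurement of
observation noise, and the variance-fraction heuristic systematically
underestimates it inside tight single-pattern clusters, which makes the
sampler carve noise into spurious sub-clusters; because those boundaries
are noise-driven, a gene's replicates straddle them at random and the gene
is lost to consensus sorting for no biological reason.

## Design choices that were genuinely open

- **Pooled clustering.** Clustering each condition separately would
  require a post-hoc matching of label spaces that no validity index can
  check; one pooled run makes the label spaces identical by construction,
  at the cost of a larger clustering problem.
- **k-means++ seeding.** With uniform random seeding, two initial
  centroids regularly land in one pattern population and split it; the
  refinement step can only split further, never merge across initial
  clusters, so such a split is permanent and its noise-driven boundary
  randomly straddles replicates. Distance-weighted seeding makes
  under-segmentation (which the DP-GP step repairs) far more likely than
  over-segmentation (which nothing repairs).
- **Consensus k rule.** Mean rank over the three indices with
  smallest-k tie-break. Any monotone combination behaves similarly on
  clean data; the report keeps all three columns so a user can override.
- **Recall accounting.** Replicate sorting deliberately abstains on genes
  with discordant replicates. With discordance probability 0.05 per
  replicate and 3-of-3 sorting, the expected fraction of shift genes with
  all replicates concordant is $0.95^3 \approx 0.857$ per dynamic
  condition — an abstention ceiling that no clustering can beat. The
  benchmark therefore reports precision over all called shift genes,
  recall over the replicate-qualified truth (the caller's decidable
  universe), and the strict recall over all truth shift genes alongside.
- **First-time-point filter.** Shifts whose two label centroids differ
  almost only at t = 0 are often start-point artifacts; an optional filter
  (`drop_t0_driven_shifts`, off by default) recategorizes a C shift as
  non-shift when the t = 0 difference carries at least 80% of the total L1
  centroid difference.

## The synthetic generator

`generate_gem` emulates the target study design: 5 ordered time points
(0, 12, 24, 48, 72 h), 3 replicates, 2 conditions, 500 genes by default.
Seven parametric shape families on the log2 scale — late rise, early rise,
transient peak at 24 h, monotone decline, dip-then-recover, flat-low,
flat-high — differ in expression level as well as dynamics, as real
pattern families do. Replicate trajectories are shape mean plus i.i.d.
Gaussian noise (sd 0.1) on the log2 scale, mapped to an FPKM-like scale by
$2^x - 1$ (clipped at 0). Off gene-conditions emit exact zeros in every
replicate at all time points. Default injected fractions: 4% A shifts, 3%
B, 3% C (50 shift genes in 500), with the off-in-both count derived from
the 15% per-condition off targets after the A/B shifts are accounted for.
Replicate discordance (probability 0.05) swaps a whole replicate to a
random other shape — the failure mode replicate sorting exists to catch —
rather than per-time-point outliers.

Two things the generator deliberately does *not* model: realistic RNA-seq
count noise (negative-binomial over reads, library-size artifacts) and a
continuum of expression levels within a pattern family. Consequently a
passing benchmark demonstrates that the machinery is correct and
well-calibrated on clusterable data; it does not show that any particular
real data set is clusterable. One interaction worth knowing about:
quantile normalization maps each column through the common reference
distribution, so wherever many genes share nearly the same value at a time
point, within-clump rank noise is projected onto the reference quantiles
and the effective noise is inflated. Real matrices, with their continuous
spread of expression levels, are much less prone to such clumps than
naively level-aligned synthetic shapes, which is why the shape library is
level-staggered.

## Numerical choices

- Soft-min and the soft-DTW forward/backward passes use max-shifted
  log-sum-exp; infinite entries contribute nothing.
- Barycenters descend by gradient steps with Armijo backtracking, so the
  objective is non-increasing; centroid updates start from the current
  centroid, which makes total k-means inertia non-increasing across
  iterations.
- Empty k-means clusters are reseeded with the trajectory farthest from
  its assigned centroid.
- GP kernels get a jitter of $10^{-8}\sigma_f^2$ on the diagonal before
  Cholesky factorization; degenerate (constant) inputs floor the
  hyperparameters at $10^{-4}$ with a warning.
- Gibbs sampling uses R's RNG stream, so every result is reproducible
  from the run seed; one global seed fans out to fixed per-stage seeds so
  stages can be rerun in isolation.
- Ties: quantile normalization averages tied ranks; `select_k` breaks
  index-rank ties toward the smallest k; set naming breaks size ties by
  signature string order; nearest-centroid assignment breaks exact
  distance ties toward the lower cluster index.

## Problem sizes used by the tests and benchmark script

The packaged benchmark (`scripts/acceptance.R`) runs the generator at its
default 500 genes (2,565 active trajectories) with k grid 3-10, a
250-gene null configuration, and a 60-gene determinism check; the unit
tests use 30-120 gene simulations and 16-60 trajectory clustering
fixtures. These sizes were chosen so the whole suite exercises every
stage, including the 1,000-sweep Gibbs refinement, at desk scale; the
k grid default of 35-90 in steps of 5 is intended for organism-scale
matrices with tens of thousands of genes.

## Known limitations

- The DP-GP hyperparameters are fixed per refined cluster (estimated
  once), not resampled; a full hyperparameter Gibbs scheme would be
  slower and non-deterministic across library versions.
- Only univariate trajectories over one shared grid are supported;
  missing time points are an error, not imputed.
- GO term ancestry is not propagated before enrichment; terms are tested
  as annotated.
- The two-step design never merges across initial clusters; a pattern
  split by the initial k-means stays split (mitigated, not eliminated, by
  distance-weighted seeding and the consensus k rule).
- With `min_agree = 2` the qualified set grows (it always contains the
  3-of-3 set), at the cost of admitting genes with one discordant
  replicate; both modes are supported, one global mode per run.
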