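---
title: "Mapping single cells onto spatial spots: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping single cells onto spatial spots}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(spotmatch)
```

## The problem and the model

Sequencing-based spatial transcriptomics reads out gene expression at
spots, each covering one to a dozen cells, so cell-type composition and
single-cell states inside a spot are latent. Given an annotated scRNA-seq
reference from the same tissue, `spotmatch` treats spot resolution as an
assignment problem: estimate how many cells each spot holds, then match
individual reference cells to sub-spot slots so that total
cell-to-spot dissimilarity is minimal. The matching is globally optimal
(exact linear sum assignment), not greedy: a cell that fits two spots well
is placed where the whole section benefits most.

Four ingredients make the cost matrix informative:

* **Cell-type-specific feature genes.** The fold change of gene *i* in
  type *j*, `FC = Y_ij / (sum_l Y_il - Y_ij) * (k - 1)`, is weighted by
  `tanh(lambda * W_i)`, where `W_i` is the gene's per-type median
  expression relative to the global median of those medians. The tanh
  factor approaches 1 for highly expressed genes and 0 for barely
  expressed ones, so seeds combine specificity with enough expression to
  survive into spot-level mixtures. Seeds are expanded by co-expression:
  genes are z-scored, PCA-compressed into a signal matrix `Q`
  (components × genes), and each gene's Pearson correlation with a type's
  mean seed column is Fisher-Z transformed (`artanh`) and tested against a
  normal null with standard error `1/sqrt(t - 3)`. Working in component
  space rather than raw cell space denoises the correlations. The union
  `G` of per-type sets is the only gene set used downstream.
* **Cluster labels for every cell.** Spot clusters (SNN + Louvain) are
  transferred to each spot's k nearest cells in a joint 2D embedding
  (CCA-style SVD integration followed by UMAP), and a random forest
  trained on those cells generalizes the labels to the full reference.
  Similarity is then computed within clusters only, which shrinks the
  assignment problems and prevents cross-region matches.
* **Per-spot cell counts.** Genes with across-spot count variance below a
  threshold ("stable genes") proxy cellular content; a spot's count is
  its stable-gene total relative to the section mean, scaled by a
  platform prior (`mean.cell.num`), rounded half-up, clamped to at least
  one cell.
* **Cosine similarity** between cells and spots over `G`, insensitive to
  depth differences between the two modalities.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `resolution_mode` | `"low"` | preset: low-resolution (Visium-class) sets `mean_cell_num = 5`, `knn_k = 5`; high-resolution sets both to 1 |
| `seed_num` | 30 | seed genes per type; 30 was the more robust of the two conventions we ship (10 remains available) |
| `lambda_weight` | 0.1 | scale of the tanh expression weight; smaller values flatten the weight, larger ones saturate it |
| `p_cutoff` | 0.01 | two-sided significance for co-expression membership |
| `var_threshold` | 0.5 | count variance below which a gene is "stable" (raw counts; a normalized-variance option exists because raw-count variance grows with depth) |
| `n_trees` | 1000 | random-forest size; accuracy plateaus well below this on separable data |
| `cca_dim` | 20 | shared-space dimensionality of the integration |
| `umap_neighbors`, `umap_min_dist` | 30, 0.3 | 2D projection; mapping quality is flat over a wide range |
| `var_explained`, `max_components` | 0.9, 50 | signal-matrix size t: smallest t explaining 90 % variance, capped |
| `rng_seed` | 42 | single seed; the entire pipeline is deterministic given it |

## Numerical choices and degenerate inputs

* Normalization is library-size scaling to 10,000 counts plus `log1p`. A
  variance-stabilizing transform can be substituted through the
  `norm_fun` hook; downstream steps consume only correlations and
  cosines, which are robust to the exact transform.
* Zero denominators in the fold change (genes expressed in exactly one
  type) are replaced by 1e-9, so such genes get large finite scores while
  equal-expression genes score exactly 1.
* `|r|` is clamped to 1 − 1e-12 before `artanh`; zero-variance genes are
  excluded from co-expression testing; `t` is forced above 3 because the
  Fisher test's standard error needs `t − 3 > 0`.
* Z-scores (both in expression standardization and in the RMSE metric)
  use the population (1/n) standard deviation.
* Rounding of cell counts is half-up; every spot is clamped to hold at
  least one cell. If no gene passes the stable-gene threshold — typical
  for multi-cell spots whose summed counts have variance above 0.5 — the
  5 % lowest-variance expressed genes are used instead, with a warning.
* Ties are deterministic everywhere: seed ranking and argmax fills break
  by gene/cell id, conflicting label transfers keep the nearest spot and
  then the first spot id, dominant types break by column order.
* When cells outnumber sub-spots the surplus is reported unassigned
  (forcing them in would violate the one-cell-per-sub-spot feasibility);
  when sub-spots outnumber cells the one-to-one problem is solved first so
  every cell is used, then remaining slots take their most similar cell,
  flagged as duplicates. Unassigned cells are not recycled across
  clusters.
* Spot clustering scales its SNN neighbour count with the section size
  (q/8, between 5 and 20): a fixed large k on small sections forces
  neighbourhoods across domains and collapses the partition.
* Fewer than 3 spots form a single cluster; fewer than 10 shared feature
  genes abort integration with an explicit count.

## The synthetic generator

`make_sc()` draws negative-binomial counts (background mean 0.5, size 2 —
sparse, overdispersed, scRNA-like) over 1,000 genes with 30 disjoint
marker genes per type elevated 8-fold in their own type; the default
fixture has 2,000 cells across 6 types. Two spot syntheses are provided:

* `simulate_st_poisson()` draws each spot's true cell count from
  Poisson(λ) (clamped ≥ 1), sums the counts of uniformly sampled cells,
  and applies multiplicative perturbation: each count is multiplied by
  `1 + e`, `e ~ N(0, noise)`, rounded half-up and clamped at zero (a
  UMI-resampling mode exists behind a flag). The optional `type_bias`
  lays spots out in one spatial domain per type, sampling the dominant
  type with probability 0.75 by default — a cluster-blocked caricature of
  tissue regions chosen as a realistic domain purity.
* `simulate_st_template()` reproduces a template-driven protocol: the
  reference is split 1:1 per type (odd types give the extra cell to the
  train half), the top variable genes of the train half (count-dispersion
  ranking) integrate it with the template, each template spot aggregates
  its `knn_k` nearest train cells in the joint embedding, noise is
  applied, and the held-out half becomes the mapping reference.

What the generator does **not** emulate: ambient RNA and doublets,
segment-level platform noise, spatial expression gradients within a
domain, unbalanced type abundances, or batch effects beyond a per-gene
shift. Passing recovery tests on these fixtures therefore demonstrates
the machinery is correct and calibrated, not that real-tissue accuracy
will match the synthetic numbers.

On the default conditions (500 template spots, 5 cells per spot, 0 %
noise) the pipeline's per-type proportion recovery runs around PCC 0.99 /
RMSE 0.02, degrading (weakly) with added noise; note that multiplicative
count noise on small counts is largely absorbed by rounding, so the
degradation between 0 % and 20 % is slight on this fixture. The problem
sizes used throughout the test-suite (hundreds of cells and tens of spots
for unit tests; the full default fixture for end-to-end checks) were
chosen to exercise every code path at desk scale.

## Benchmark metrics

Per cell type, across spots: PCC; SSIM on columns min-max scaled to
[0, 1] with constants `C1 = 0.01`, `C2 = 0.03` entering as squares (the
numerator uses `2*u*ũ` as printed in the convention we follow — users
comparing against image-processing SSIM implementations should note the
difference); RMSE on z-scored columns (affine-invariant by construction);
Jensen–Shannon divergence of the normalized spatial distributions
(natural log by default, base 2 optional; bounded by log 2). Per dataset:
ACCU, the fraction of spots whose dominant predicted type matches the
truth. Across methods: AS, the mean of the five per-metric ranks (best =
N), normalized by the number of methods N into (0, 1] — the normalization
makes scores comparable across benchmark panels of different size. The
ground-truth-free alternative is the spot-level correlation between
predicted proportions and marker-signature scores (rank-sum markers,
expression-bin-matched background), and spatial layering can be
quantified with the k-distance (mean distance to the k = 10 nearest
reference cells).

## Open choices we fixed

* Seed count 10 vs 30: both conventions exist in the field; 30 is the
  default here, 10 is a config value.
* The Fisher z-test's effective sample size is the number of retained
  components t.
* Correlation with a type's seeds uses the mean seed column in signal
  space (single well-defined vector, stable when seeds are few), not a
  mean of pairwise correlations.
* A gene may belong to several types' feature sets; only the union feeds
  the pipeline, so deduplication is unnecessary.
* Random-forest features are the normalized (not raw, not scaled)
  expression of `G`.
* Cell-to-spot distances default to the 2D UMAP plane; a `space = "cca"`
  option keeps the pre-2D shared space for users who prefer distances
  over principal directions.
* Variable genes are ranked by raw count dispersion (variance/mean)
  rather than bin-standardized dispersion: on data with strong marker
  blocks, whole mean-bins consist of markers and within-bin z-scoring
  erases exactly the signal the step must keep.
* The spot-level clustering resolution (0.8) and neighbour heuristic are
  this package's choices; they are exposed in the configuration.

## Known limitations

* Sub-spots are bookkeeping slots, not geometry: assigned cells inherit
  their spot's coordinates (plus optional deterministic jitter for
  plotting), and no sub-cellular placement is inferred.
* Clusters with spots but no predicted cells leave those spots empty
  (warned); clusters partition the problem, so a poor spot clustering
  caps achievable accuracy.
* Raw-count stable-gene variance is depth-sensitive; for sections with
  strong depth gradients use `use_norm = TRUE` in `stable_genes()`.
* The method assumes the reference covers the types present in the
  section; unrepresented types are necessarily mis-assigned.
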