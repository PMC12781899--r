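# spotmatch

Sequencing-based spatial transcriptomics (ST) measures expression at
*spots* that each capture a small mixture of cells, while scRNA-seq resolves
single cells but loses their positions. `spotmatch` maps annotated single
cells from an scRNA-seq reference onto ST spots at single-cell resolution,
producing a spatial single-cell map and per-spot cell-type proportions. It
is aimed at anyone who has a paired (same tissue) annotated SC dataset and
an ST section — Visium-class low-resolution data as well as
high-resolution platforms (Slide-seq V2, Visium HD, Stereo-seq, MERFISH).

## Method

Given SC counts X (m genes × n cells, k annotated types) and ST counts S
(p genes × q spots with 2D coordinates), the pipeline:

1. **Preprocessing** — library-size + log1p normalization of both
   datasets; graph-based clustering (SNN + Louvain on top PCs) of the
   spots into c clusters.
2. **Feature genes** — per-type means Y (m × k); fold change
   FC_ij = Y_ij / (Σ_l Y_il − Y_ij) · (k−1); weighted
   FC′_ij = tanh(λ·W_i) · FC_ij with W_i the gene's median expression
   relative to the global median of medians (λ = 0.1), so lowly expressed
   genes are suppressed; the top `seed_num` (default 30) genes per type
   become seeds. Genes are z-scored and PCA-reduced into a signal matrix Q
   (t components × m genes); each gene's correlation r with a type's mean
   seed column is Fisher-Z transformed, z′ = artanh(r), and tested against
   N(0, 1/(t−3)); genes with p < 0.01 join the type's set. The union G of
   all sets drives everything downstream.
3. **Label transfer** — SC and ST restricted to G are integrated by a
   CCA-style SVD of the cross-product of the gene-standardized matrices,
   projected to 2D with UMAP; each spot's k nearest cells (k = 1
   high-resolution, k = 5 low-resolution) inherit its cluster label; a
   1000-tree random forest trained on these cells predicts a cluster label
   for every cell.
4. **Cell counts** — genes with across-spot count variance < 0.5 are
   "stable genes"; a spot's cell count is
   round(spot.expr / spot.mean · mean.cell.num), clamped to ≥ 1
   (mean.cell.num = 5 low-resolution, 1 high-resolution).
5. **Assignment** — within each cluster, cosine similarity between cells
   and spots over G; each spot is expanded into one sub-spot per estimated
   cell, and cells are matched to sub-spots by an exact linear sum
   assignment (Jonker–Volgenant-class solver) minimizing Σ (1 − simi)·A.
   Surplus cells are reported unassigned; scarce cells are reused with a
   duplicate flag.

Benchmarks included: per-type PCC, SSIM, z-score RMSE, Jensen–Shannon
divergence, spot-level mapping accuracy (ACCU), a rank-aggregated accuracy
score (AS) across methods, ground-truth-free spot-level signature
correlation, and spatial k-distance. A synthetic generator produces paired
SC/ST fixtures (negative-binomial counts with planted marker blocks;
Poisson or template-driven spot synthesis) so every stage is testable
without downloads.

## Worked example

```r
library(spotmatch)

sc  <- make_sc(generator_spec(n_types = 4, n_genes = 300, n_cells = 400,
                              markers_per_type = 15, seed = 7))
sim <- simulate_st_poisson(sc, n_spots = 80, lambda = 5, perturbation = 0.01,
                           seed = 7, type_bias = 0.75)
res <- run_map(sc, sim$st, spot_config("low", rng_seed = 11))
print(res)
#> cell_assignment: 398 cell-to-sub-spot pairs over 80 spots; 28 duplicated, 30 unassigned cells

report <- run_benchmark(sim$truth$proportions, res$proportions)
print(report)
#> metrics_report over 4 cell types:
#>    pcc   ssim   rmse     js   accu
#> 0.9408 0.9289 0.3428 0.0544 0.9375

cor(res$counts$n_s, sim$truth$n_true)
#> 0.919
```

398 of the 400 cells were placed into sub-spots (the remaining spots'
estimated capacity was filled by duplicating the most similar cells, 28
flags; 30 surplus cells stay unassigned rather than being forced in).
Against the generating truth, the per-spot cell-type proportions reach a
mean per-type Pearson correlation of 0.94 and the dominant type is correct
in 94 % of spots; the estimated per-spot cell counts correlate at r = 0.92
with the true Poisson draws. `run_map(..., outdir = )` additionally writes
`assignment.tsv` (cell → spot/sub-spot with coordinates),
`proportions.csv`, the seed-gene audit tables, a config snapshot and a run
log.

A thin command-line front-end wraps the same functions:

```sh
exec/spotmatch simulate --outdir fixtures --n-spots 200 --lambda 5 --seed 1
exec/spotmatch map --sc fixtures/sc --annotations fixtures/annotations.tsv \
    --st fixtures/st --coords fixtures/coords.csv --mode low --outdir out
```

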