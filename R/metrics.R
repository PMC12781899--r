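#' Benchmark metrics for spot-composition recovery
#'
#' Per-cell-type metrics comparing a predicted spots x types composition
#' matrix against ground truth: Pearson correlation (PCC), structural
#' similarity (SSIM, on columns min-max scaled to `[0, 1]`), RMSE on z-scored
#' columns, and Jensen-Shannon divergence of the spatial distribution of
#' each type. Dataset-level metrics: mapping accuracy (ACCU) of the
#' dominant type per spot and, across methods, the rank-aggregated accuracy
#' score (AS).
#'
#' @name benchmark-metrics
NULL

#' @describeIn benchmark-metrics Pearson correlation of one type's
#'   composition across spots. Returns `NA` with a warning for constant
#'   columns.
#' @param truth,pred Numeric vectors (composition of one cell type across
#'   spots) or, for [metric_accu()], per-spot labels.
#' @export
metric_pcc <- function(truth, pred) {
  if (stats::sd(truth) == 0 || stats::sd(pred) == 0) {
    warning("constant composition column; PCC undefined")
    return(NA_real_)
  }
  stats::cor(truth, pred)
}

#' @describeIn benchmark-metrics Structural similarity with constants
#'   C1 = 0.01, C2 = 0.03 entering as squares; both columns are min-max
#'   scaled to `[0, 1]` first (zero-range columns scale to zeros).
#' @param C1,C2 SSIM stabilization constants.
#' @export
metric_ssim <- function(truth, pred, C1 = 0.01, C2 = 0.03) {
  x <- .minmax(truth); y <- .minmax(pred)
  ux <- mean(x); uy <- mean(y)
  vx <- stats::var(x); vy <- stats::var(y)
  cv <- stats::cov(x, y)
  ((2 * ux * uy + C1^2) * (2 * cv + C2^2)) /
    ((ux^2 + uy^2 + C1^2) * (vx + vy + C2^2))
}

.minmax <- function(x) {
  r <- range(x)
  if (r[1] == r[2]) return(rep(0, length(x)))
  (x - r[1]) / (r[2] - r[1])
}

#' @describeIn benchmark-metrics Root mean squared error between the
#'   z-scores of the two columns (constant columns z-score to 0 with a
#'   warning), so affine transforms of a column are not penalized.
#' @export
metric_rmse <- function(truth, pred) {
  sqrt(mean((.zscore(truth) - .zscore(pred))^2))
}

# Population-sd z-scores, consistent with the z-normalization used on the
# expression side (1/n denominator).
.zscore <- function(x) {
  mu <- mean(x)
  s <- sqrt(mean((x - mu)^2))
  if (s == 0) {
    warning("constant column; z-scores set to 0")
    return(rep(0, length(x)))
  }
  (x - mu) / s
}

#' @describeIn benchmark-metrics Jensen-Shannon divergence between the two
#'   columns normalized to probability vectors; `0 log 0 := 0`; bounded by
#'   log 2 in the chosen base.
#' @param base Logarithm base (default `exp(1)`; use 2 for bits).
#' @export
metric_js <- function(truth, pred, base = exp(1)) {
  if (sum(truth) == 0 || sum(pred) == 0) stop("zero-sum composition column")
  p <- truth / sum(truth)
  q <- pred / sum(pred)
  m <- (p + q) / 2
  0.5 * .kl(q, m, base) + 0.5 * .kl(p, m, base)
}

.kl <- function(a, b, base) {
  nz <- a > 0
  sum(a[nz] * log(a[nz] / b[nz], base = base))
}

#' @describeIn benchmark-metrics Fraction of spots whose predicted cell
#'   type matches the truth. For composition matrices use
#'   [dominant_type()] first.
#' @export
metric_accu <- function(truth, pred) {
  stopifnot(length(truth) == length(pred))
  mean(truth == pred)
}

#' Dominant cell type per spot
#'
#' The type with the highest proportion in each row; ties resolved by
#' column order (documented, deterministic).
#'
#' @param proportions Spots x types matrix.
#' @return Character vector of type labels, one per spot.
#' @export
dominant_type <- function(proportions) {
  colnames(proportions)[max.col(proportions, ties.method = "first")]
}

#' Rank-aggregated accuracy score across methods
#'
#' Each method's mean PCC, SSIM and ACCU are ranked ascending (best rank =
#' number of methods N) and mean RMSE and JS descending (lowest value gets
#' rank N); ties receive average ranks. AS is the mean of the five ranks,
#' normalized by N into (0, 1].
#'
#' @param means Data frame / matrix with one row per method and columns
#'   `pcc`, `ssim`, `accu`, `rmse`, `js`.
#' @return Named numeric vector of normalized AS values.
#' @export
accuracy_score <- function(means) {
  means <- as.data.frame(means)
  stopifnot(all(c("pcc", "ssim", "accu", "rmse", "js") %in% names(means)),
            nrow(means) >= 2)
  N <- nrow(means)
  rk <- cbind(rank(means$pcc), rank(means$ssim), rank(means$accu),
              rank(-means$rmse), rank(-means$js))
  as <- rowMeans(rk) / N
  stats::setNames(as, rownames(means))
}

#' Full metrics report for one prediction
#'
#' @param truth,pred Spots x types composition matrices (matching dimnames;
#'   rows sum to 1).
#' @param base JS logarithm base.
#' @return List of class `metrics_report`: `per_type` data frame (pcc, ssim,
#'   rmse, js per type), `accu`, and column means.
#' @export
benchmark_composition <- function(truth, pred, base = exp(1)) {
  stopifnot(all(dim(truth) == dim(pred)))
  pred <- pred[rownames(truth), colnames(truth), drop = FALSE]
  per_type <- data.frame(
    type = colnames(truth),
    pcc = vapply(seq_len(ncol(truth)),
                 function(i) suppressWarnings(metric_pcc(truth[, i], pred[, i])),
                 numeric(1)),
    ssim = vapply(seq_len(ncol(truth)),
                  function(i) metric_ssim(truth[, i], pred[, i]), numeric(1)),
    rmse = vapply(seq_len(ncol(truth)),
                  function(i) suppressWarnings(metric_rmse(truth[, i], pred[, i])),
                  numeric(1)),
    js = vapply(seq_len(ncol(truth)),
                function(i) metric_js(truth[, i], pred[, i], base), numeric(1)),
    row.names = NULL)
  accu <- metric_accu(dominant_type(truth), dominant_type(pred))
  structure(list(per_type = per_type, accu = accu,
                 means = c(pcc = mean(per_type$pcc, na.rm = TRUE),
                           ssim = mean(per_type$ssim),
                           rmse = mean(per_type$rmse),
                           js = mean(per_type$js),
                           accu = accu)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("metrics_report over", nrow(x$per_type), "cell types:\n")
  print(round(x$means, 4))
  invisible(x)
}

#' Spot-level correlation against marker signature scores
#'
#' Ground-truth-free evaluation: per cell type, markers are the top
#' `n_markers` genes by log fold change among genes significant in a
#' two-sided rank-sum test (SC data, that type vs the rest); each spot's
#' signature score is the mean normalized expression of the markers minus
#' that of an equal-sized, expression-bin-matched background draw. The
#' returned value per spot is the Pearson correlation, across types,
#' between its predicted proportion vector and its score vector.
#'
#' @param proportions Spots x types predicted composition.
#' @param st A `spatial_dataset` with `norm` filled.
#' @param sc An `annotated_sc` with `norm` filled (marker source).
#' @param n_markers Markers per type (100 default; 10 suits low-plex panels).
#' @param n_bins Expression bins for background matching (default 25).
#' @param seed Seed for the background draw.
#' @return Named numeric vector of per-spot correlations (`NA` where
#'   undefined).
#' @export
spot_level_correlation <- function(proportions, st, sc, n_markers = 100L,
                                   n_bins = 25L, seed = 42L) {
  types <- colnames(proportions)
  if (length(types) < 2) stop("need at least 2 cell types")
  markers <- find_markers(sc, n_markers = n_markers)
  stn <- .dense(.need_norm(st))
  scores <- .with_seed(seed, vapply(types, function(ty) {
    .module_score(stn, markers[[ty]], n_bins)
  }, numeric(ncol(stn))))
  out <- vapply(seq_len(nrow(proportions)), function(j) {
    p <- proportions[j, ]
    s <- scores[j, ]
    if (stats::sd(p) == 0 || stats::sd(s) == 0) return(NA_real_)
    stats::cor(p, s)
  }, numeric(1))
  stats::setNames(out, rownames(proportions))
}

# Mean signature expression minus mean of bin-matched background genes.
.module_score <- function(stn, sig, n_bins) {
  sig <- intersect(sig, rownames(stn))
  avg <- rowMeans(stn)
  bins <- cut(rank(avg, ties.method = "first"), breaks = n_bins, labels = FALSE)
  names(bins) <- rownames(stn)
  bg <- unlist(lapply(sig, function(g) {
    pool <- setdiff(names(bins)[bins == bins[g]], sig)
    if (length(pool) == 0) return(character(0))
    pool[sample.int(length(pool), 1)]
  }), use.names = FALSE)
  if (length(bg) == 0) return(rep(NA_real_, ncol(stn)))
  colMeans(stn[sig, , drop = FALSE]) - colMeans(stn[bg, , drop = FALSE])
}

#' Per-type marker genes by rank-sum test
#'
#' Vectorized two-sided Wilcoxon rank-sum (normal approximation) of each
#' gene in the cells of one type against all other cells, keeping genes
#' with p < `p_cutoff` and positive log fold change, ranked by log fold
#' change.
#'
#' @param sc An `annotated_sc` with `norm` filled.
#' @param n_markers Markers per type.
#' @param p_cutoff Significance cutoff (default 0.01).
#' @return Named list of marker gene-id vectors per type.
#' @export
find_markers <- function(sc, n_markers = 100L, p_cutoff = 0.01) {
  norm <- .dense(.need_norm(sc))
  ranks <- matrixStats::rowRanks(norm, ties.method = "average")
  n <- ncol(norm)
  types <- sort(unique(sc$cell_type))
  out <- lapply(types, function(ty) {
    grp <- sc$cell_type == ty
    n1 <- sum(grp); n2 <- n - n1
    r1 <- rowSums(ranks[, grp, drop = FALSE])
    u <- r1 - n1 * (n1 + 1) / 2
    mu <- n1 * n2 / 2
    sig <- sqrt(n1 * n2 * (n + 1) / 12)
    p <- 2 * stats::pnorm(-abs(u - mu) / sig)
    lfc <- log2((rowMeans(norm[, grp, drop = FALSE]) + 1e-9) /
                (rowMeans(norm[, !grp, drop = FALSE]) + 1e-9))
    keep <- which(p < p_cutoff & lfc > 0)
    keep <- keep[order(-lfc[keep], rownames(norm)[keep], method = "radix")]
    rownames(norm)[utils::head(keep, n_markers)]
  })
  stats::setNames(out, types)
}

#' Spatial k-distance
#'
#' Mean Euclidean distance from each query point to its k nearest reference
#' points; quantifies spatial layering of one population relative to
#' another.
#'
#' @param query_coords,reference_coords Two-column coordinate matrices.
#' @param k Neighbours (default 10); reduced with a warning if the
#'   reference is smaller.
#' @return Numeric vector, one mean distance per query point.
#' @export
k_distance <- function(query_coords, reference_coords, k = 10L) {
  nref <- nrow(reference_coords)
  if (k > nref) {
    warning("k reduced to ", nref, " (reference has only ", nref, " points)")
    k <- nref
  }
  nn <- RANN::nn2(reference_coords, query = query_coords, k = k)
  rowMeans(nn$nn.dists)
}
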