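#' Cosine similarity between cells and spots
#'
#' Columns (cells, spots) are compared over the shared feature genes:
#' simi_ij = sum_k x_ki s_kj / (||x_i|| ||s_j||). Zero-norm columns get
#' similarity 0 with a warning. Typically called once per cluster with the
#' cells predicted into, and the spots assigned to, that cluster.
#'
#' @param cells Genes x cells matrix (normalized, restricted to G).
#' @param spots Genes x spots matrix (same genes, same order).
#' @return Cells x spots similarity matrix with id dimnames.
#' @export
cosine_similarity <- function(cells, spots) {
  cells <- .dense(cells); spots <- .dense(spots)
  stopifnot(nrow(cells) == nrow(spots))
  cn <- sqrt(colSums(cells^2))
  sn <- sqrt(colSums(spots^2))
  if (any(cn == 0) || any(sn == 0)) {
    warning("zero-norm column(s); their similarities set to 0")
    cn[cn == 0] <- Inf
    sn[sn == 0] <- Inf
  }
  crossprod(cells, spots) / outer(cn, sn)
}

#' Identify stable genes across spots
#'
#' Genes whose count variance across spots (unbiased, n-1 denominator) is
#' below the threshold; their consistent expression makes total stable-gene
#' counts a proxy for cellular content. If no gene qualifies, the 5%
#' lowest-variance expressed genes are used with a warning.
#'
#' @param st A `spatial_dataset`.
#' @param var_threshold Variance cutoff (default 0.5).
#' @param use_norm Compute variance on the normalized layer instead of raw
#'   counts (raw-count variance is sequencing-depth sensitive).
#' @return Character vector of gene ids, sorted by variance ascending.
#' @export
stable_genes <- function(st, var_threshold = 0.5, use_norm = FALSE) {
  m <- .dense(if (use_norm) .need_norm(st) else st$counts)
  v <- matrixStats::rowVars(m)
  names(v) <- rownames(m)
  keep <- v < var_threshold
  if (!any(keep)) {
    warning("no gene below the variance threshold; falling back to the 5% ",
            "lowest-variance expressed genes")
    expressed <- rowSums(m) > 0
    vv <- v[expressed]
    keep_ids <- names(sort(vv))[seq_len(max(1L, ceiling(0.05 * length(vv))))]
    return(keep_ids)
  }
  names(sort(v[keep]))
}

#' Estimate the number of cells in each spot
#'
#' The total stable-gene count of a spot (`spot_expr`), relative to the
#' across-spot mean (`spot_mean`), scales the platform prior
#' `mean_cell_num` into a per-spot cell count, rounded half-up and clamped
#' to at least one cell.
#'
#' @param st A `spatial_dataset`.
#' @param genes Stable gene ids from [stable_genes()].
#' @param mean_cell_num Assumed average cells per spot (1 high-res, 5 low-res).
#' @return List with `n_s` (integer counts by spot id), `N` (total
#'   sub-spots), `spot_expr`, `spot_mean`, `stable_genes`.
#' @export
estimate_counts <- function(st, genes, mean_cell_num = 5L) {
  if (length(genes) == 0) stop("empty stable gene set")
  expr <- Matrix::colSums(st$counts[genes, , drop = FALSE])
  spot_mean <- mean(expr)
  if (spot_mean == 0) stop("stable genes carry no signal (spot mean = 0)")
  n <- pmax(1L, as.integer(floor(expr / spot_mean * mean_cell_num + 0.5)))
  names(n) <- st$spot_ids
  list(n_s = n, N = sum(n), spot_expr = expr, spot_mean = spot_mean,
       stable_genes = genes)
}
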