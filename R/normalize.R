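#' Normalize a count matrix
#'
#' Default transform: scale every cell/spot to a fixed total (10,000), then
#' log1p. A pluggable hook (`norm_fun`) replaces the transform wholesale —
#' e.g. with Pearson-residual style variance stabilization — for users who
#' want closer agreement with other toolchains; every downstream step uses
#' only correlations and cosines and is robust to the exact transform.
#'
#' @param data An `annotated_sc` or `spatial_dataset`.
#' @param scale_factor Per-column target total (default 10,000).
#' @param norm_fun Optional `function(counts) -> matrix` hook.
#' @return The same object with the `norm` layer filled.
#' @export
normalize_data <- function(data, scale_factor = 1e4, norm_fun = NULL) {
  stopifnot(inherits(data, "annotated_sc") || inherits(data, "spatial_dataset"))
  counts <- data$counts
  if (!is.null(norm_fun)) {
    norm <- norm_fun(counts)
    stopifnot(all(dim(norm) == dim(counts)))
  } else {
    totals <- Matrix::colSums(counts)
    zero <- totals == 0
    if (any(zero)) {
      warning(sum(zero), " all-zero column(s); normalized to zeros")
      totals[zero] <- 1
    }
    if (inherits(counts, "Matrix")) {
      norm <- counts %*% Matrix::Diagonal(x = scale_factor / totals)
      norm@x <- log1p(norm@x)
      dimnames(norm) <- dimnames(counts)
    } else {
      norm <- log1p(sweep(counts, 2, totals, "/") * scale_factor)
    }
  }
  data$norm <- norm
  data
}

.need_norm <- function(data) {
  if (is.null(data$norm)) stop("normalized layer missing; run normalize_data() first")
  data$norm
}

#' Cluster spatial spots
#'
#' Graph-based community detection in the style of the standard single-cell
#' workflow: top principal components of the scaled normalized layer, a
#' shared-nearest-neighbor graph with Jaccard weights, then Louvain at the
#' given resolution. Labels are contiguous integers from 0, ordered by
#' decreasing cluster size, and deterministic for a fixed seed.
#'
#' @param st A `spatial_dataset` with the `norm` layer filled.
#' @param resolution Louvain resolution (default 0.8).
#' @param n_pcs Number of principal components (default 30).
#' @param snn_k Neighbours for the SNN graph. Default scales with the spot
#'   count (q/8, between 5 and 20) so small sections are not forced into
#'   cross-domain neighbourhoods.
#' @param seed RNG seed.
#' @return `st` with `cluster` filled.
#' @export
cluster_spots <- function(st, resolution = 0.8, n_pcs = 30L, snn_k = NULL,
                          seed = 42L) {
  norm <- .need_norm(st)
  q <- ncol(norm)
  if (q < 3) {
    st$cluster <- stats::setNames(rep(0L, q), st$spot_ids)
    return(st)
  }
  if (is.null(snn_k)) snn_k <- min(20L, max(5L, q %/% 8L))
  emb <- .pca_cells(norm, n_pcs, seed)
  snn_k <- min(snn_k, q - 1L)
  nn <- RANN::nn2(emb, k = snn_k + 1L)$nn.idx
  adj <- .snn_jaccard(nn)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  memb <- .with_seed(seed, igraph::membership(
    igraph::cluster_louvain(g, resolution = resolution)))
  labels <- .relabel_by_size(as.integer(memb))
  st$cluster <- stats::setNames(labels, st$spot_ids)
  st
}

# PCA over columns (cells/spots): returns columns x n_pcs scores.
.pca_cells <- function(norm, n_pcs, seed = 42L) {
  x <- t(.dense(norm))                     # cells x genes
  x <- scale(x, center = TRUE, scale = FALSE)
  n_pcs <- min(n_pcs, dim(x) - 1L)
  if (min(dim(x)) <= 100 || n_pcs >= min(dim(x)) %/% 2) {
    sv <- svd(x, nu = n_pcs, nv = 0)
    emb <- sv$u %*% diag(sv$d[seq_len(n_pcs)], n_pcs)
  } else {
    sv <- .with_seed(seed, irlba::irlba(x, nv = n_pcs))
    emb <- sv$u %*% diag(sv$d, n_pcs)
  }
  rownames(emb) <- rownames(x)
  emb
}

.snn_jaccard <- function(nn_idx) {
  n <- nrow(nn_idx)
  k <- ncol(nn_idx)
  ind <- Matrix::sparseMatrix(i = rep(seq_len(n), k), j = as.vector(nn_idx),
                              x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(ind)
  jac <- shared / (2 * k - shared)
  jac@x[jac@x < 1 / 15] <- 0           # prune weak links as the SNN workflow does
  Matrix::drop0(jac)
}

.relabel_by_size <- function(labels) {
  sizes <- sort(table(labels), decreasing = TRUE)
  map <- stats::setNames(seq_along(sizes) - 1L, names(sizes))
  as.integer(map[as.character(labels)])
}
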