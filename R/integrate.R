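#' Integrate SC and ST expression over the feature genes
#'
#' CCA-style joint projection: both normalized matrices are restricted to
#' the shared feature genes, each gene is standardized within its dataset
#' (removing per-dataset shifts and scale), and the SVD of the cross-product
#' of the two standardized matrices yields a shared d-dimensional space in
#' which every cell and spot vector is L2-normalized.
#'
#' @param sc An `annotated_sc` with `norm` filled.
#' @param st A `spatial_dataset` with `norm` filled.
#' @param genes Feature gene ids (list G); intersected with both datasets.
#' @param d Shared-space dimensionality (default 20).
#' @param seed RNG seed for the truncated SVD.
#' @return List of class `joint_embedding` with `cell_coords` (n x d),
#'   `spot_coords` (q x d), `d_cca`, `genes`.
#' @export
integrate_datasets <- function(sc, st, genes, d = 20L, seed = 42L) {
  shared <- intersect(intersect(genes, sc$gene_ids), st$gene_ids)
  if (length(shared) < 10) {
    stop("only ", length(shared), " shared feature genes between SC and ST; need >= 10")
  }
  X <- .std_genes(.dense(.need_norm(sc))[shared, , drop = FALSE])
  S <- .std_genes(.dense(.need_norm(st))[shared, , drop = FALSE])
  d <- min(d, ncol(X) - 1L, ncol(S) - 1L, length(shared) - 1L)
  K <- crossprod(X, S)                    # cells x spots
  if (min(dim(K)) <= 100 || d >= min(dim(K)) %/% 3) {
    sv <- svd(K, nu = d, nv = d)
    u <- sv$u; v <- sv$v
  } else {
    sv <- .with_seed(seed, irlba::irlba(K, nv = d))
    u <- sv$u; v <- sv$v
  }
  cell <- .l2_rows(u[, seq_len(d), drop = FALSE])
  spot <- .l2_rows(v[, seq_len(d), drop = FALSE])
  rownames(cell) <- sc$cell_ids
  rownames(spot) <- st$spot_ids
  structure(list(cell_coords = cell, spot_coords = spot, d_cca = d,
                 genes = shared),
            class = "joint_embedding")
}

.std_genes <- function(m) {
  mu <- rowMeans(m)
  sd <- sqrt(rowMeans((m - mu)^2))
  sd[sd == 0] <- 1
  (m - mu) / sd
}

.l2_rows <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  nrm[nrm == 0] <- 1
  m / nrm
}

#' Project the joint space to 2D
#'
#' UMAP of the stacked cell and spot vectors. Deterministic for a fixed
#' seed (single-threaded layout optimization). Cell-spot distances used by
#' label transfer are Euclidean distances in this plane; a `space = "cca"`
#' option keeps the pre-2D shared space instead for users preferring
#' distances over principal directions.
#'
#' @param emb A `joint_embedding` from [integrate_datasets()].
#' @param seed RNG seed.
#' @param n_neighbors,min_dist UMAP parameters (defaults 30, 0.3).
#' @param space `"umap"` (default) or `"cca"` (skip the 2D projection).
#' @return The embedding with `cell_coords`/`spot_coords` replaced by the
#'   distance-space coordinates.
#' @export
embed_2d <- function(emb, seed = 42L, n_neighbors = 30L, min_dist = 0.3,
                     space = c("umap", "cca")) {
  space <- match.arg(space)
  if (space == "cca") return(emb)
  all_pts <- rbind(emb$cell_coords, emb$spot_coords)
  n_tot <- nrow(all_pts)
  if (n_neighbors >= n_tot) {
    warning("n_neighbors reduced to ", n_tot - 1L, " (only ", n_tot, " points)")
    n_neighbors <- n_tot - 1L
  }
  coords <- .with_seed(seed, uwot::umap(
    all_pts, n_neighbors = n_neighbors, min_dist = min_dist,
    n_threads = 1, n_sgd_threads = 0, n_components = 2))
  n <- nrow(emb$cell_coords)
  emb$cell_coords <- coords[seq_len(n), , drop = FALSE]
  emb$spot_coords <- coords[-seq_len(n), , drop = FALSE]
  rownames(emb$cell_coords) <- rownames(all_pts)[seq_len(n)]
  rownames(emb$spot_coords) <- rownames(all_pts)[-seq_len(n)]
  emb
}

#' Transfer spot cluster labels to nearest cells
#'
#' Each spot's k nearest cells (Euclidean distance in the embedding) receive
#' the spot's cluster label. A cell selected by several spots keeps the
#' label of the nearest one; exact distance ties go to the spot id that
#' sorts first.
#'
#' @param emb A `joint_embedding` (after [embed_2d()]).
#' @param st A `spatial_dataset` with `cluster` filled.
#' @param k Cells per spot (default 5; use 1 for high-resolution data).
#' @return Data frame (`cell_id`, `spot_id`, `cluster`, `dist`), one row per
#'   transferred cell.
#' @export
transfer_labels <- function(emb, st, k = 5L) {
  if (is.null(st$cluster)) stop("spot clusters missing; run cluster_spots() first")
  n <- nrow(emb$cell_coords)
  if (k > n) stop("k (", k, ") exceeds the number of cells (", n, ")")
  nn <- RANN::nn2(emb$cell_coords, query = emb$spot_coords, k = k)
  spots <- rownames(emb$spot_coords)
  cand <- data.frame(
    cell_id = rownames(emb$cell_coords)[as.vector(nn$nn.idx)],
    spot_id = rep(spots, times = k),
    dist = as.vector(nn$nn.dists),
    stringsAsFactors = FALSE)
  cand$cluster <- st$cluster[cand$spot_id]
  ord <- order(cand$dist, cand$spot_id, method = "radix")
  cand <- cand[ord, ]
  cand <- cand[!duplicated(cand$cell_id), ]
  rownames(cand) <- NULL
  cand[, c("cell_id", "spot_id", "cluster", "dist")]
}

#' Train the cluster-label random forest
#'
#' Features are the normalized expression of the feature genes in the
#' transferred cells; the response is the transferred spot cluster label.
#'
#' @param transfer Output of [transfer_labels()].
#' @param sc An `annotated_sc` with `norm` filled.
#' @param genes Feature gene ids used during integration.
#' @param n_trees Number of trees (default 1000).
#' @param seed RNG seed.
#' @return List of class `cluster_model` with the fitted forest (or a
#'   degenerate constant model when only one label is present), `genes`,
#'   `labels`, and the out-of-bag error.
#' @export
train_rf <- function(transfer, sc, genes, n_trees = 1000L, seed = 42L) {
  genes <- intersect(genes, sc$gene_ids)
  feats <- t(.dense(.need_norm(sc))[genes, transfer$cell_id, drop = FALSE])
  colnames(feats) <- make.names(genes)
  y <- factor(transfer$cluster)
  if (nlevels(y) < 2) {
    warning("single cluster label in the transfer set; using a constant model")
    return(structure(list(forest = NULL, constant = levels(y),
                          genes = genes, labels = levels(y), oob = 0),
                     class = "cluster_model"))
  }
  rf <- .with_seed(seed, randomForest::randomForest(
    x = feats, y = y, ntree = n_trees))
  structure(list(forest = rf, constant = NULL, genes = genes,
                 labels = levels(y), oob = rf$err.rate[n_trees, "OOB"]),
            class = "cluster_model")
}

#' Predict cluster labels for every cell
#'
#' @param model A `cluster_model` from [train_rf()].
#' @param sc An `annotated_sc` with `norm` filled.
#' @return Integer cluster labels named by cell id.
#' @export
predict_clusters <- function(model, sc) {
  missing <- setdiff(model$genes, sc$gene_ids)
  if (length(missing) > 0) {
    stop("SC data lacks ", length(missing), " training feature genes (e.g. ",
         paste(utils::head(missing, 3), collapse = ", "), ")")
  }
  if (!is.null(model$constant)) {
    lab <- rep(model$constant, ncol(sc$counts))
  } else {
    feats <- t(.dense(.need_norm(sc))[model$genes, , drop = FALSE])
    colnames(feats) <- make.names(model$genes)
    lab <- as.character(stats::predict(model$forest, feats))
  }
  stats::setNames(as.integer(lab), sc$cell_ids)
}
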