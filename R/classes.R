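#' Annotated single-cell expression dataset
#'
#' Bundles a genes x cells count matrix with per-cell cell-type labels.
#' Counts are stored genes-as-rows; a normalized layer (`norm`) is filled by
#' [normalize_data()].
#'
#' @param counts Non-negative matrix (base or `Matrix` sparse), genes x cells,
#'   with unique rownames (gene ids) and colnames (cell ids).
#' @param cell_type Character vector of cell-type labels, one per cell, either
#'   named by cell id or in column order of `counts`.
#' @param norm Optional normalized layer of the same shape.
#' @return An object of class `annotated_sc` with fields `counts`, `norm`,
#'   `gene_ids`, `cell_ids`, `cell_type`.
#' @export
annotated_sc <- function(counts, cell_type, norm = NULL) {
  counts <- .as_count_matrix(counts, what = "cell")
  if (is.null(names(cell_type))) {
    if (length(cell_type) != ncol(counts)) {
      stop("cell_type must have one label per cell (", ncol(counts), " cells)")
    }
    names(cell_type) <- colnames(counts)
  }
  missing <- setdiff(colnames(counts), names(cell_type))
  if (length(missing) > 0) {
    stop("cell_type annotation missing for cells: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  cell_type <- as.character(cell_type[colnames(counts)])
  names(cell_type) <- colnames(counts)
  if (anyNA(cell_type)) stop("cell_type contains NA labels")
  obj <- structure(
    list(counts = counts, norm = norm,
         gene_ids = rownames(counts), cell_ids = colnames(counts),
         cell_type = cell_type),
    class = "annotated_sc")
  obj
}

#' Spatial transcriptomics dataset
#'
#' Genes x spots count matrix plus 2D spot coordinates. Spot cluster labels
#' (`cluster`, integers from 0) are filled by [cluster_spots()].
#'
#' @param counts Non-negative matrix, genes x spots, unique dimnames.
#' @param coords Two-column matrix/data.frame of spot coordinates (x, y),
#'   rows named by spot id or ordered as the columns of `counts`.
#' @param norm Optional normalized layer.
#' @param cluster Optional integer cluster labels named by spot id.
#' @return An object of class `spatial_dataset` with fields `counts`, `norm`,
#'   `gene_ids`, `spot_ids`, `coords`, `cluster`.
#' @export
spatial_dataset <- function(counts, coords, norm = NULL, cluster = NULL) {
  counts <- .as_count_matrix(counts, what = "spot")
  coords <- as.matrix(coords[, 1:2, drop = FALSE])
  storage.mode(coords) <- "double"
  if (is.null(rownames(coords))) {
    if (nrow(coords) != ncol(counts)) stop("coords must have one row per spot")
    rownames(coords) <- colnames(counts)
  }
  missing <- setdiff(colnames(counts), rownames(coords))
  if (length(missing) > 0) {
    stop("coords missing for spots: ", paste(utils::head(missing, 5), collapse = ", "))
  }
  coords <- coords[colnames(counts), , drop = FALSE]
  colnames(coords) <- c("x", "y")
  if (!all(is.finite(coords))) stop("spot coordinates must be finite")
  if (!is.null(cluster)) {
    cluster <- .check_cluster_labels(cluster, colnames(counts))
  }
  structure(
    list(counts = counts, norm = norm,
         gene_ids = rownames(counts), spot_ids = colnames(counts),
         coords = coords, cluster = cluster),
    class = "spatial_dataset")
}

.check_cluster_labels <- function(cluster, spot_ids) {
  if (is.null(names(cluster))) names(cluster) <- spot_ids
  cluster <- as.integer(cluster[spot_ids])
  if (anyNA(cluster)) stop("cluster labels missing for some spots")
  names(cluster) <- spot_ids
  cluster
}

.as_count_matrix <- function(counts, what = "cell") {
  if (is.data.frame(counts)) counts <- as.matrix(counts)
  if (!inherits(counts, "Matrix")) counts <- as.matrix(counts)
  if (nrow(counts) < 1 || ncol(counts) < 1) stop("count matrix must be non-empty")
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("count matrix needs gene rownames and ", what, " colnames")
  }
  if (anyDuplicated(rownames(counts))) counts <- .collapse_duplicate_genes(counts)
  if (anyDuplicated(colnames(counts))) stop(what, " ids must be unique")
  vals <- if (inherits(counts, "Matrix")) counts@x else counts
  if (any(vals < 0)) stop("counts must be non-negative")
  if (any(vals != floor(vals))) {
    warning("non-integer counts detected; flooring")
    counts <- floor(counts)
  }
  counts
}

# Duplicate gene symbols are summed, not dropped, so MTX and CSV dialects agree.
.collapse_duplicate_genes <- function(counts) {
  ids <- rownames(counts)
  f <- factor(ids, levels = unique(ids))
  agg <- Matrix::sparse.model.matrix(~ 0 + f)  # rows: original, cols: unique
  out <- Matrix::t(agg) %*% counts
  rownames(out) <- levels(f)
  if (!inherits(counts, "Matrix")) out <- as.matrix(out)
  out
}

#' Pipeline configuration
#'
#' Collects every tunable parameter of the mapping pipeline. The
#' `resolution_mode` preset follows platform resolution: high-resolution
#' platforms (Slide-seq V2, Visium HD, Stereo-seq, MERFISH) use one cell per
#' spot and k = 1 nearest neighbours for label transfer; low-resolution
#' platforms (10x Visium) use five cells per spot and k = 5.
#'
#' @param resolution_mode `"low"` or `"high"`; sets `mean_cell_num` and
#'   `knn_k` unless these are given explicitly.
#' @param mean_cell_num Assumed average cells per spot.
#' @param knn_k Nearest single cells per spot during label transfer.
#' @param seed_num Seed genes per cell type (default 30; the alternative
#'   top-10 convention is available by setting `seed_num = 10`).
#' @param lambda_weight Scaling factor of the tanh expression weight
#'   (default 0.1).
#' @param var_threshold Across-spot count variance below which a gene is
#'   "stable" (default 0.5).
#' @param p_cutoff Co-expression significance cutoff (default 0.01).
#' @param n_trees Random-forest tree count (default 1000).
#' @param rng_seed Global seed making the whole pipeline deterministic.
#' @param cluster_resolution Louvain resolution for spot clustering.
#' @param n_pcs Principal components for spot clustering.
#' @param cca_dim Shared-space dimensionality for SC/ST integration.
#' @param umap_neighbors,umap_min_dist 2D projection parameters.
#' @param var_explained,max_components Signal-matrix component selection:
#'   smallest t explaining `var_explained` of variance, capped at
#'   `max_components`.
#' @param jitter_radius Deterministic plotting jitter radius for mapped cell
#'   coordinates; 0 disables.
#' @param norm_fun Optional normalization hook `function(counts) -> matrix`
#'   replacing the default library-size + log1p transform.
#' @return A list of class `spot_config`.
#' @export
spot_config <- function(resolution_mode = c("low", "high"),
                        mean_cell_num = NULL, knn_k = NULL,
                        seed_num = 30L, lambda_weight = 0.1,
                        var_threshold = 0.5, p_cutoff = 0.01,
                        n_trees = 1000L, rng_seed = 42L,
                        cluster_resolution = 0.8, n_pcs = 30L,
                        cca_dim = 20L, umap_neighbors = 30L,
                        umap_min_dist = 0.3,
                        var_explained = 0.9, max_components = 50L,
                        jitter_radius = 0, norm_fun = NULL) {
  resolution_mode <- match.arg(resolution_mode)
  preset <- if (resolution_mode == "high") list(mcn = 1L, k = 1L) else list(mcn = 5L, k = 5L)
  if (is.null(mean_cell_num)) mean_cell_num <- preset$mcn
  if (is.null(knn_k)) knn_k <- preset$k
  stopifnot(mean_cell_num >= 1, knn_k >= 1, seed_num >= 1,
            lambda_weight > 0, var_threshold > 0,
            p_cutoff > 0, p_cutoff < 1, n_trees >= 1)
  structure(list(
    resolution_mode = resolution_mode,
    mean_cell_num = as.integer(mean_cell_num), knn_k = as.integer(knn_k),
    seed_num = as.integer(seed_num), lambda_weight = lambda_weight,
    var_threshold = var_threshold, p_cutoff = p_cutoff,
    n_trees = as.integer(n_trees), rng_seed = as.integer(rng_seed),
    cluster_resolution = cluster_resolution, n_pcs = as.integer(n_pcs),
    cca_dim = as.integer(cca_dim), umap_neighbors = as.integer(umap_neighbors),
    umap_min_dist = umap_min_dist, var_explained = var_explained,
    max_components = as.integer(max_components),
    jitter_radius = jitter_radius, norm_fun = norm_fun),
    class = "spot_config")
}

#' @export
print.annotated_sc <- function(x, ...) {
  cat("annotated_sc:", nrow(x$counts), "genes x", ncol(x$counts), "cells,",
      length(unique(x$cell_type)), "cell types;",
      if (is.null(x$norm)) "no" else "with", "normalized layer\n")
  invisible(x)
}

#' @export
print.spatial_dataset <- function(x, ...) {
  cat("spatial_dataset:", nrow(x$counts), "genes x", ncol(x$counts), "spots;",
      if (is.null(x$cluster)) "unclustered"
      else paste(length(unique(x$cluster)), "clusters"), "\n")
  invisible(x)
}

#' @export
print.spot_config <- function(x, ...) {
  cat("spot_config (", x$resolution_mode, "-resolution preset)\n", sep = "")
  for (f in setdiff(names(x), "norm_fun")) cat("  ", f, ": ", x[[f]], "\n", sep = "")
  invisible(x)
}

# Evaluate an expression under a temporary RNG state; the caller's stream
# is untouched so pipeline stages can be seeded independently.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

.dense <- function(m) {
  if (inherits(m, "Matrix")) as.matrix(m) else m
}
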