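#' Specification for the synthetic SC generator
#'
#' Negative-binomial background with disjoint marker blocks: each type's
#' marker genes are elevated `marker_fold`-fold in that type only. Defaults
#' describe the package's standard study fixture: 2,000 cells over 6 types,
#' 1,000 genes, 30 markers per type at 8-fold elevation.
#'
#' @param n_types Number of cell types.
#' @param n_genes Total genes.
#' @param n_cells Total cells (split as evenly as possible across types).
#' @param markers_per_type Disjoint marker genes per type.
#' @param marker_fold Mean elevation of a marker in its own type.
#' @param mu_bg,size Negative-binomial background mean and dispersion.
#' @param seed Generator seed.
#' @return A list of class `generator_spec`.
#' @export
generator_spec <- function(n_types = 6L, n_genes = 1000L, n_cells = 2000L,
                           markers_per_type = 30L, marker_fold = 8,
                           mu_bg = 0.5, size = 2, seed = 1L) {
  if (n_types * markers_per_type > n_genes) {
    stop("marker sets must be disjoint: n_types * markers_per_type exceeds n_genes")
  }
  structure(list(n_types = as.integer(n_types), n_genes = as.integer(n_genes),
                 n_cells = as.integer(n_cells),
                 markers_per_type = as.integer(markers_per_type),
                 marker_fold = marker_fold, mu_bg = mu_bg, size = size,
                 seed = as.integer(seed)),
            class = "generator_spec")
}

#' Generate an annotated synthetic SC dataset
#'
#' @param spec A [generator_spec()].
#' @return An [annotated_sc()]; the planted markers are recorded in
#'   `attr(, "markers")` (list per type).
#' @export
make_sc <- function(spec = generator_spec()) {
  .with_seed(spec$seed, {
    m <- spec$n_genes; n <- spec$n_cells; k <- spec$n_types
    types <- sprintf("type%02d", seq_len(k))
    per <- diff(floor(seq(0, n, length.out = k + 1)))
    labels <- rep(types, per)
    genes <- sprintf("gene%04d", seq_len(m))
    markers <- split(genes[seq_len(k * spec$markers_per_type)],
                     rep(types, each = spec$markers_per_type))
    mu <- matrix(spec$mu_bg, m, n)
    for (ty in types) {
      mu[match(markers[[ty]], genes), labels == ty] <- spec$mu_bg * spec$marker_fold
    }
    counts <- matrix(stats::rnbinom(m * n, mu = mu, size = spec$size), m, n,
                     dimnames = list(genes, sprintf("cell%05d", seq_len(n))))
    sc <- annotated_sc(counts, stats::setNames(labels, colnames(counts)))
    attr(sc, "markers") <- markers
    sc
  })
}

#' Simulate ST data by Poisson sampling of cells per spot
#'
#' Each spot draws a true cell count from Poisson(lambda) (clamped to at
#' least 1), samples that many cells uniformly without replacement, sums
#' their counts, and applies multiplicative transcriptional perturbation.
#' Spots are laid on a square grid.
#'
#' @param sc An `annotated_sc`.
#' @param n_spots Number of spots.
#' @param lambda Poisson mean of cells per spot.
#' @param perturbation Noise level: each count is multiplied by
#'   (1 + e), e ~ N(0, perturbation), rounded half-up, clamped at 0.
#'   `mode = "resample"` instead resamples that fraction of UMIs.
#' @param seed RNG seed.
#' @param mode Perturbation mode, `"multiplicative"` (default) or
#'   `"resample"`.
#' @param type_bias Optional: lay spots out in one spatial domain per cell
#'   type (vertical grid bands) and sample that fraction of each spot's
#'   cells from the domain's dominant type, the rest uniformly. `NULL`
#'   (default) samples uniformly, with no spatial structure.
#' @return List with `st` (a `spatial_dataset`) and `truth` (per-spot cell
#'   ids, true counts `n_true`, true type `proportions`, parameters).
#' @export
simulate_st_poisson <- function(sc, n_spots = 200L, lambda = 5,
                                perturbation = 0.01, seed = 1L,
                                mode = c("multiplicative", "resample"),
                                type_bias = NULL) {
  mode <- match.arg(mode)
  stopifnot(lambda > 0)
  if (n_spots < 1) stop("n_spots must be >= 1")
  .with_seed(seed, {
    n_cells <- ncol(sc$counts)
    n_true <- pmax(1L, stats::rpois(n_spots, lambda))
    side <- ceiling(sqrt(n_spots))
    coords <- cbind(x = (seq_len(n_spots) - 1) %% side,
                    y = (seq_len(n_spots) - 1) %/% side)
    spot_ids <- sprintf("spot%04d", seq_len(n_spots))
    rownames(coords) <- spot_ids
    types <- sort(unique(sc$cell_type))
    domain <- if (!is.null(type_bias)) {
      types[pmin(length(types),
                 1 + floor(coords[, "x"] / (side / length(types))))]
    } else NULL
    members <- lapply(seq_len(n_spots), function(s) {
      if (is.null(domain)) {
        sample.int(n_cells, n_true[s], replace = n_true[s] > n_cells)
      } else {
        own <- which(sc$cell_type == domain[s])
        n_dom <- stats::rbinom(1, n_true[s], type_bias)
        c(sample(own, min(n_dom, length(own))),
          sample.int(n_cells, n_true[s] - min(n_dom, length(own))))
      }
    })
    counts <- vapply(members, function(idx) {
      Matrix::rowSums(sc$counts[, idx, drop = FALSE])
    }, numeric(nrow(sc$counts)))
    dimnames(counts) <- list(sc$gene_ids, spot_ids)
    counts <- .perturb_counts(counts, perturbation, mode)
    st <- spatial_dataset(counts, coords)
    prop <- .truth_proportions(members, sc, spot_ids)
    list(st = st,
         truth = list(cells = lapply(members, function(i) sc$cell_ids[i]),
                      n_true = stats::setNames(n_true, spot_ids),
                      proportions = prop,
                      params = list(lambda = lambda, perturbation = perturbation,
                                    seed = seed, type_bias = type_bias)))
  })
}

.perturb_counts <- function(counts, level, mode = "multiplicative") {
  if (level <= 0) return(counts)
  if (mode == "multiplicative") {
    e <- matrix(stats::rnorm(length(counts), 0, level), nrow(counts))
    pmax(floor(counts * (1 + e) + 0.5), 0)
  } else {
    # resample `level` of all UMIs across genes within each spot
    apply(counts, 2, function(col) {
      tot <- sum(col)
      k <- floor(level * tot + 0.5)
      if (k == 0 || tot == 0) return(col)
      drop <- stats::rmultinom(1, k, prob = col / tot)[, 1]
      add <- stats::rmultinom(1, k, prob = rep(1 / length(col), length(col)))[, 1]
      pmax(col - drop, 0) + add
    })
  }
}

.truth_proportions <- function(members, sc, spot_ids) {
  types <- sort(unique(sc$cell_type))
  prop <- t(vapply(members, function(idx) {
    tab <- table(factor(sc$cell_type[idx], levels = types))
    as.numeric(tab / sum(tab))
  }, numeric(length(types))))
  dimnames(prop) <- list(spot_ids, types)
  prop
}

#' Stratified train/test split of SC data
#'
#' Per-type 1:1 split (train receives the extra cell of odd-sized types).
#'
#' @param sc An `annotated_sc`.
#' @param ratio Train fraction (default 0.5).
#' @param seed RNG seed.
#' @return List with `train` and `test` `annotated_sc` objects.
#' @export
split_train_test <- function(sc, ratio = 0.5, seed = 1L) {
  sizes <- table(sc$cell_type)
  if (any(sizes < 2)) {
    stop("every cell type needs >= 2 cells; too small: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  idx_train <- .with_seed(seed, {
    unlist(lapply(sort(unique(sc$cell_type)), function(ty) {
      own <- which(sc$cell_type == ty)
      sample(own, ceiling(ratio * length(own)))
    }), use.names = FALSE)
  })
  idx_train <- sort(idx_train)
  keep <- function(idx) {
    annotated_sc(sc$counts[, idx, drop = FALSE], sc$cell_type[idx])
  }
  list(train = keep(idx_train), test = keep(setdiff(seq_len(ncol(sc$counts)), idx_train)))
}

#' Simulate ST data from a spatial template
#'
#' Reproduces the template-driven protocol: the SC data is split 1:1 per
#' type; the top variable genes of the train half are used to integrate it
#' with the template; each template spot aggregates the counts of its
#' `knn_k` nearest train cells in the joint 2D embedding; transcriptional
#' noise is applied; the held-out test half is returned as the mapping
#' reference.
#'
#' @param sc An `annotated_sc` (counts; normalization handled internally).
#' @param template A `spatial_dataset` providing coordinates and expression.
#' @param knn_k Cells aggregated per spot (1 = high-resolution, 5 = low).
#' @param noise Noise level (0, 0.05, 0.20 in the standard protocol).
#' @param n_hvg Variable genes used for the integration (default 2000).
#' @param seed RNG seed.
#' @return List with `st`, `truth` (as in [simulate_st_poisson()]) and
#'   `reference` (the held-out test `annotated_sc`).
#' @export
simulate_st_template <- function(sc, template, knn_k = 5L, noise = 0,
                                 n_hvg = 2000L, seed = 1L) {
  if (is.null(template$coords)) stop("template must carry spot coordinates")
  halves <- split_train_test(sc, 0.5, seed = seed)
  train <- normalize_data(halves$train)
  tmpl <- normalize_data(template)
  hvg <- variable_genes(train, n_hvg)
  hvg <- intersect(hvg, tmpl$gene_ids)
  emb <- integrate_datasets(train, tmpl, hvg, d = 20L, seed = seed)
  emb <- embed_2d(emb, seed = seed)
  nn <- RANN::nn2(emb$cell_coords, query = emb$spot_coords, k = knn_k)
  members <- split(as.vector(t(nn$nn.idx)), rep(seq_len(nrow(nn$nn.idx)), each = knn_k))
  counts <- vapply(members, function(idx) {
    Matrix::rowSums(train$counts[, idx, drop = FALSE])
  }, numeric(nrow(train$counts)))
  dimnames(counts) <- list(train$gene_ids, template$spot_ids)
  counts <- .with_seed(seed + 1L, .perturb_counts(counts, noise))
  st <- spatial_dataset(counts, template$coords)
  prop <- .truth_proportions(members, train, template$spot_ids)
  list(st = st,
       truth = list(cells = lapply(members, function(i) train$cell_ids[i]),
                    n_true = stats::setNames(rep(knn_k, ncol(counts)),
                                             template$spot_ids),
                    proportions = prop,
                    params = list(knn_k = knn_k, noise = noise,
                                  n_hvg = n_hvg, seed = seed)),
       reference = halves$test)
}

#' Top variable genes by count dispersion
#'
#' Genes are ranked by dispersion (variance/mean of raw counts) descending;
#' under a negative-binomial background the dispersion of an unstructured
#' gene stays near 1 + mu/size, so genes with type-structured expression
#' stand out. Ties break by gene id for determinism.
#'
#' @param sc An `annotated_sc`.
#' @param n Number of genes (default 2000).
#' @return Character vector of gene ids.
#' @export
variable_genes <- function(sc, n = 2000L) {
  m <- .dense(sc$counts)
  mu <- rowMeans(m)
  disp <- ifelse(mu > 0, matrixStats::rowVars(m) / mu, 0)
  ord <- order(-disp, rownames(m), method = "radix")
  rownames(m)[utils::head(ord, n)]
}
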