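#' Mean normalized expression per cell type
#'
#' @param sc An `annotated_sc` with the `norm` layer filled.
#' @return Matrix Y (genes x types) of per-type mean normalized expression.
#' @export
type_means <- function(sc) {
  norm <- .need_norm(sc)
  types <- sort(unique(sc$cell_type))
  if (length(types) < 2) stop("fold change needs at least 2 cell types")
  Y <- vapply(types, function(ty) {
    Matrix::rowMeans(norm[, sc$cell_type == ty, drop = FALSE])
  }, numeric(nrow(norm)))
  dimnames(Y) <- list(sc$gene_ids, types)
  Y
}

#' Per-type fold change of each gene
#'
#' FC of gene i in type j is its mean expression divided by the summed mean
#' expression over the other k-1 types, rescaled by (k-1) so a gene expressed
#' equally in all types has FC exactly 1. Zero denominators (genes expressed
#' in exactly one type) are replaced by a small epsilon, keeping FC finite
#' and larger than any non-degenerate gene's value.
#'
#' @param Y Output of [type_means()].
#' @param eps Denominator guard (default 1e-9).
#' @return Matrix (genes x types) of FC values.
#' @export
fold_change <- function(Y, eps = 1e-9) {
  k <- ncol(Y)
  if (k < 2) stop("fold change needs at least 2 cell types")
  other <- rowSums(Y) - Y
  other[other == 0] <- eps
  Y / other * (k - 1)
}

#' Expression-weighted fold change
#'
#' Each gene's FC is damped by tanh(lambda * W), where W is the gene's
#' per-type median expression relative to the global median of those
#' medians. Lowly expressed genes get weights near 0 and are suppressed;
#' for highly expressed genes the factor saturates at 1.
#'
#' @param Y Output of [type_means()].
#' @param fc Output of [fold_change()].
#' @param lambda Weight scale (default 0.1).
#' @return List with `w` (gene weights) and `fc_prime` (weighted FC matrix).
#' @export
seed_weights <- function(Y, fc, lambda = 0.1) {
  med <- matrixStats::rowMedians(Y)
  global <- stats::median(med)
  if (global == 0) stop("global median of per-gene medians is 0; data too sparse")
  w <- med / global
  fcp <- tanh(lambda * w) * fc
  dimnames(fcp) <- dimnames(fc)
  list(w = stats::setNames(w, rownames(Y)), fc_prime = fcp)
}

#' Select seed genes per cell type
#'
#' Top `seed_num` genes per type by weighted fold change, descending; exact
#' ties are broken by gene id (C-locale lexicographic) for determinism.
#'
#' @param fc_prime Weighted FC matrix from [seed_weights()].
#' @param seed_num Genes per type (default 30).
#' @return Named list, one ordered character vector of gene ids per type.
#' @export
select_seeds <- function(fc_prime, seed_num = 30L) {
  m <- nrow(fc_prime)
  if (m < seed_num) {
    warning("only ", m, " genes available; taking all as seeds")
    seed_num <- m
  }
  ids <- rownames(fc_prime)
  out <- lapply(colnames(fc_prime), function(ty) {
    ord <- order(-fc_prime[, ty], ids, method = "radix")
    ids[ord[seq_len(seed_num)]]
  })
  stats::setNames(out, colnames(fc_prime))
}

#' PCA signal matrix of genes
#'
#' Genes are z-scored across cells (population standard deviation); PCA of
#' the cells x genes matrix retains the smallest number of components t
#' explaining at least `var_explained` of total variance (capped at
#' `max_components`). The returned Q (t x genes) holds each gene's
#' component-space representation (loadings scaled by singular values), used
#' for noise-reduced gene-gene correlation.
#'
#' @param sc An `annotated_sc` with `norm` filled.
#' @param var_explained Variance fraction target (default 0.9).
#' @param max_components Cap on t (default 50).
#' @param seed RNG seed for the truncated SVD.
#' @return List with `Q` (t x genes), `t`, `zero_var` (gene ids excluded
#'   from co-expression testing).
#' @export
signal_matrix <- function(sc, var_explained = 0.9, max_components = 50L,
                          seed = 42L) {
  norm <- .dense(.need_norm(sc))
  n <- ncol(norm)
  mu <- rowMeans(norm)
  sd_pop <- sqrt(rowMeans((norm - mu)^2))
  zero_var <- sd_pop == 0
  z <- (norm - mu) / ifelse(zero_var, 1, sd_pop)
  z[zero_var, ] <- 0
  x <- t(z)                               # cells x genes
  kmax <- min(max_components, dim(x) - 1L)
  if (min(dim(x)) <= 100 || kmax >= min(dim(x)) %/% 3) {
    sv <- svd(x)
    d <- sv$d[seq_len(min(kmax, length(sv$d)))]
    v <- sv$v[, seq_along(d), drop = FALSE]
  } else {
    sv <- .with_seed(seed, irlba::irlba(x, nv = kmax))
    d <- sv$d
    v <- sv$v
  }
  total <- sum(x^2)                       # Frobenius norm = total variance * n
  cum <- cumsum(d^2) / total
  t_sel <- which(cum >= var_explained)[1]
  if (is.na(t_sel)) t_sel <- length(d)
  t_sel <- max(t_sel, min(4L, length(d))) # Fisher z-test needs t > 3
  Q <- t(v[, seq_len(t_sel), drop = FALSE] %*% diag(d[seq_len(t_sel)], t_sel))
  colnames(Q) <- rownames(z)
  list(Q = Q, t = t_sel, zero_var = rownames(z)[zero_var])
}

#' Expand seed genes by significant co-expression
#'
#' For each cell type, every gene's Pearson correlation r with the mean
#' signal-space column of the type's seed genes is Fisher-Z transformed,
#' z' = artanh(r), and tested two-sided against N(0, 1/(t-3)). Genes with
#' p below `p_cutoff` join the type's feature set; seeds always belong to
#' their own set. The union over types is the feature gene list G.
#'
#' @param signal Output of [signal_matrix()].
#' @param seeds Output of [select_seeds()].
#' @param p_cutoff Significance cutoff (default 0.01).
#' @return List with `per_type` (list of gene-id vectors) and `G` (union).
#' @export
coexpression_expand <- function(signal, seeds, p_cutoff = 0.01) {
  Q <- signal$Q
  t_comp <- signal$t
  if (t_comp <= 3) stop("need t > 3 signal components for the Fisher z-test; got ",
                        t_comp, " - increase max_components or data size")
  testable <- setdiff(colnames(Q), signal$zero_var)
  Qt <- Q[, testable, drop = FALSE]
  se <- 1 / sqrt(t_comp - 3)
  per_type <- lapply(names(seeds), function(ty) {
    ref <- rowMeans(Q[, seeds[[ty]], drop = FALSE])
    if (stats::sd(ref) == 0) return(seeds[[ty]])
    r <- as.vector(stats::cor(Qt, ref))
    r <- pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
    z <- atanh(r)
    p <- 2 * stats::pnorm(-abs(z) / se)
    union(seeds[[ty]], testable[p < p_cutoff])
  })
  names(per_type) <- names(seeds)
  G <- sort(unique(unlist(per_type)))
  if (length(G) == 0) stop("empty feature gene list")
  list(per_type = per_type, G = G)
}

#' Full feature-gene selection
#'
#' Runs [type_means()], [fold_change()], [seed_weights()], [select_seeds()],
#' [signal_matrix()] and [coexpression_expand()] with the parameters of a
#' [spot_config()].
#'
#' @param sc An `annotated_sc` with `norm` filled.
#' @param config A `spot_config`.
#' @return List with `Y`, `fc`, `w`, `fc_prime`, `seeds`, `signal`,
#'   `per_type`, `G`.
#' @export
select_features <- function(sc, config = spot_config()) {
  Y <- type_means(sc)
  fc <- fold_change(Y)
  sw <- seed_weights(Y, fc, lambda = config$lambda_weight)
  seeds <- select_seeds(sw$fc_prime, seed_num = config$seed_num)
  sig <- signal_matrix(sc, var_explained = config$var_explained,
                       max_components = config$max_components,
                       seed = config$rng_seed)
  fs <- coexpression_expand(sig, seeds, p_cutoff = config$p_cutoff)
  list(Y = Y, fc = fc, w = sw$w, fc_prime = sw$fc_prime, seeds = seeds,
       signal = sig, per_type = fs$per_type, G = fs$G)
}

#' Export the seed-gene table and feature list for audits
#'
#' @param features Output of [select_features()].
#' @param outdir Output directory.
#' @return Paths of the written TSVs, invisibly.
#' @export
export_features <- function(features, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  rows <- do.call(rbind, lapply(names(features$seeds), function(ty) {
    g <- features$seeds[[ty]]
    data.frame(gene_id = g, type = ty,
               fc = features$fc[g, ty], w = features$w[g],
               fc_prime = features$fc_prime[g, ty], rank = seq_along(g))
  }))
  spath <- file.path(outdir, "seed_genes.tsv")
  gpath <- file.path(outdir, "feature_genes.tsv")
  utils::write.table(rows, spath, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(features$G, gpath)
  invisible(c(seeds = spath, features = gpath))
}
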