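# Shared fixture builders and independent oracles.

# Small annotated SC object from an explicit matrix.
tiny_sc <- function(counts, types) {
  if (is.null(rownames(counts))) rownames(counts) <- paste0("g", seq_len(nrow(counts)))
  if (is.null(colnames(counts))) colnames(counts) <- paste0("c", seq_len(ncol(counts)))
  annotated_sc(counts, stats::setNames(types, colnames(counts)))
}

# Small spatial dataset on a line of spots.
tiny_st <- function(counts) {
  if (is.null(rownames(counts))) rownames(counts) <- paste0("g", seq_len(nrow(counts)))
  if (is.null(colnames(counts))) colnames(counts) <- paste0("s", seq_len(ncol(counts)))
  coords <- cbind(x = seq_len(ncol(counts)), y = 0)
  rownames(coords) <- colnames(counts)
  spatial_dataset(counts, coords)
}

# Standard small planted-marker fixture used across module tests.
small_fixture <- function(seed = 7, n_types = 4, n_genes = 300, n_cells = 400,
                          markers_per_type = 15, marker_fold = 8) {
  make_sc(generator_spec(n_types = n_types, n_genes = n_genes,
                         n_cells = n_cells,
                         markers_per_type = markers_per_type,
                         marker_fold = marker_fold, seed = seed))
}

# Brute-force minimum assignment cost: minimum over all injections of the
# smaller side into the larger, by exhaustive permutation enumeration.
# cost: cells x sub-spots matrix. Independent of the package's solver.
brute_min_cost <- function(cost) {
  n <- nrow(cost); N <- ncol(cost)
  if (n >= N) {
    # choose a distinct cell per sub-spot
    best <- Inf
    perm_rec <- function(j, used, acc) {
      if (acc >= best) return()
      if (j > N) { best <<- acc; return() }
      for (i in seq_len(n)) if (!used[i]) {
        used[i] <- TRUE
        perm_rec(j + 1, used, acc + cost[i, j])
        used[i] <- FALSE
      }
    }
    perm_rec(1, rep(FALSE, n), 0)
    best
  } else {
    brute_min_cost(t(cost))
  }
}
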