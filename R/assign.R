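#' Expand a similarity matrix into sub-spot columns
#'
#' Each spot estimated to hold n_s cells is expanded into n_s sub-spots by
#' replicating its similarity column n_s times; columns are ordered by
#' (spot id, replicate index).
#'
#' @param simi Cells x spots similarity matrix (id dimnames).
#' @param counts Output of [estimate_counts()] (or any named integer vector
#'   in `$n_s` covering the spots of `simi`).
#' @return List with `mat` (cells x N), `spot_of` (spot id per column),
#'   `replicate_of` (0-based replicate index per column).
#' @export
expand_subspots <- function(simi, counts) {
  n_s <- counts$n_s[colnames(simi)]
  if (anyNA(n_s)) stop("cell-count estimates missing for some spots")
  idx <- rep(seq_len(ncol(simi)), times = n_s)
  mat <- simi[, idx, drop = FALSE]
  spot_of <- colnames(simi)[idx]
  replicate_of <- unlist(lapply(n_s, function(k) seq_len(k) - 1L), use.names = FALSE)
  colnames(mat) <- paste0(spot_of, "#", replicate_of)
  list(mat = mat, spot_of = spot_of, replicate_of = replicate_of)
}

#' Optimally assign cells to sub-spots within one cluster
#'
#' Minimizes the total cost sum(1 - similarity) over one-to-one matchings
#' (linear sum assignment, solved exactly). When cells outnumber sub-spots
#' (n' >= N) every sub-spot receives a distinct cell and leftover cells are
#' reported unassigned. When sub-spots outnumber cells (n' < N) the
#' one-to-one problem is solved first so every cell is used, then each
#' remaining sub-spot is filled with its most similar cell (duplicates
#' permitted and flagged; argmax ties go to the cell id sorting first).
#'
#' @param expansion Output of [expand_subspots()].
#' @return List of class `cluster_assignment`: data frame `pairs`
#'   (`cell_id`, `spot_id`, `sub_spot`, `duplicated`), `unassigned_cells`,
#'   `cost` (total assignment cost of the matched pairs).
#' @export
solve_assignment <- function(expansion) {
  mat <- .dense(expansion$mat)
  n <- nrow(mat); N <- ncol(mat)
  stopifnot(n >= 1, N >= 1)
  cost <- 1 - mat
  cost <- cost - min(cost, 0)             # LSAP needs non-negative entries
  if (n >= N) {
    sol <- clue::solve_LSAP(t(cost))      # rows = sub-spots <= columns = cells
    cell_idx <- as.integer(sol)
    sub_idx <- seq_len(N)
    dup <- rep(FALSE, N)
    unassigned <- rownames(mat)[-cell_idx]
  } else {
    sol <- clue::solve_LSAP(cost)         # rows = cells <= columns = sub-spots
    sub_idx <- as.integer(sol)
    cell_idx <- seq_len(n)
    remaining <- setdiff(seq_len(N), sub_idx)
    if (length(remaining) > 0) {
      ids <- rownames(mat)
      fill <- vapply(remaining, function(j) {
        col <- mat[, j]
        best <- which(col == max(col))
        best[order(ids[best], method = "radix")[1]]
      }, integer(1))
      cell_idx <- c(cell_idx, fill)
      sub_idx <- c(sub_idx, remaining)
    }
    dup <- c(rep(FALSE, n), rep(TRUE, length(sub_idx) - n))
    unassigned <- character(0)
  }
  ord <- order(sub_idx)
  pairs <- data.frame(
    cell_id = rownames(mat)[cell_idx][ord],
    spot_id = expansion$spot_of[sub_idx][ord],
    sub_spot = expansion$replicate_of[sub_idx][ord],
    duplicated = dup[ord],
    stringsAsFactors = FALSE)
  structure(list(pairs = pairs, unassigned_cells = unassigned,
                 cost = sum(1 - mat[cbind(cell_idx, sub_idx)])),
            class = "cluster_assignment")
}

#' Aggregate per-cluster assignments into a full-section mapping
#'
#' Concatenates the cluster solutions, attaches each cell's annotated type
#' and its spot's coordinates (with optional deterministic jitter for
#' plotting), and derives per-spot cell-type proportions.
#'
#' @param cluster_assignments List of `cluster_assignment`, one per cluster
#'   (names = cluster labels).
#' @param st The clustered `spatial_dataset`.
#' @param sc The `annotated_sc` that supplied the cells.
#' @param jitter_radius Uniform jitter radius around the spot centre
#'   (0 disables; draws are seeded).
#' @param seed Seed for the jitter draw.
#' @return List of class `cell_assignment`: `pairs` (with `cluster`,
#'   `cell_type`, `x`, `y`), `proportions` (spots x types, rows sum to 1),
#'   `unassigned_cells`, `empty_spots`.
#' @export
aggregate_assignments <- function(cluster_assignments, st, sc,
                                  jitter_radius = 0, seed = 42L) {
  pieces <- lapply(names(cluster_assignments), function(z) {
    p <- cluster_assignments[[z]]$pairs
    if (nrow(p) > 0) p$cluster <- as.integer(z)
    p
  })
  pairs <- do.call(rbind, pieces[vapply(pieces, nrow, 1L) > 0])
  if (is.null(pairs)) {
    pairs <- data.frame(cell_id = character(0), spot_id = character(0),
                        sub_spot = integer(0), duplicated = logical(0),
                        cluster = integer(0))
  }
  pairs$cell_type <- unname(sc$cell_type[pairs$cell_id])
  xy <- st$coords[pairs$spot_id, , drop = FALSE]
  if (jitter_radius > 0 && nrow(pairs) > 0) {
    jit <- .with_seed(seed, {
      ang <- stats::runif(nrow(pairs), 0, 2 * pi)
      rad <- jitter_radius * sqrt(stats::runif(nrow(pairs)))
      cbind(rad * cos(ang), rad * sin(ang))
    })
    xy <- xy + jit
  }
  pairs$x <- xy[, 1]
  pairs$y <- xy[, 2]
  pairs$sub_spot_index <- pairs$sub_spot
  empty <- setdiff(st$spot_ids, unique(pairs$spot_id))
  if (length(empty) > 0) {
    warning(length(empty), " spot(s) received no cells; excluded from proportions")
  }
  types <- sort(unique(sc$cell_type))
  occupied <- setdiff(st$spot_ids, empty)
  tab <- unclass(table(factor(pairs$spot_id, levels = occupied),
                       factor(pairs$cell_type, levels = types)))
  prop <- tab / rowSums(tab)
  unassigned <- unlist(lapply(cluster_assignments, `[[`, "unassigned_cells"),
                       use.names = FALSE)
  structure(list(pairs = pairs, proportions = prop,
                 unassigned_cells = unassigned, empty_spots = empty),
            class = "cell_assignment")
}

#' @export
print.cell_assignment <- function(x, ...) {
  cat("cell_assignment:", nrow(x$pairs), "cell-to-sub-spot pairs over",
      length(unique(x$pairs$spot_id)), "spots;",
      sum(x$pairs$duplicated), "duplicated,",
      length(x$unassigned_cells), "unassigned cells\n")
  invisible(x)
}
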