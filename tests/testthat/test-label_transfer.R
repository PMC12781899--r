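# Helper: an integrated pair from a planted-marker SC and a domain-biased ST.
integration_fixture <- function(seed = 19) {
  sc <- normalize_data(small_fixture(seed = seed))
  sim <- simulate_st_poisson(sc, n_spots = 60, lambda = 5, perturbation = 0,
                             seed = seed, type_bias = 0.9)
  st <- normalize_data(sim$st)
  st <- cluster_spots(st, seed = seed)
  list(sc = sc, st = st, truth = sim$truth)
}

test_that("self-integration places matching cells and spots together", {
  sc <- normalize_data(small_fixture(seed = 23, n_cells = 40, n_genes = 80))
  counts <- sc$counts
  colnames(counts) <- paste0("s", seq_len(ncol(counts)))
  coords <- cbind(seq_len(ncol(counts)), 0)
  rownames(coords) <- colnames(counts)
  st <- normalize_data(spatial_dataset(counts, coords))
  emb <- integrate_datasets(sc, st, sc$gene_ids, d = 10)
  d_self <- sqrt(rowSums((emb$cell_coords - emb$spot_coords)^2))
  expect_lt(max(d_self), 1e-6)
})

test_that("gene standardization removes per-gene batch shifts", {
  sc <- normalize_data(small_fixture(seed = 29, n_cells = 60, n_genes = 80))
  shift <- runif(80, 0.5, 2)
  counts <- sc$counts
  colnames(counts) <- paste0("s", seq_len(ncol(counts)))
  coords <- cbind(seq_len(ncol(counts)), 0)
  rownames(coords) <- colnames(counts)
  st <- spatial_dataset(counts, coords)
  st$norm <- as.matrix(sc$norm) + shift    # constant per-gene offset
  emb <- integrate_datasets(sc, st, sc$gene_ids, d = 10)
  paired <- sqrt(rowSums((emb$cell_coords - emb$spot_coords)^2))
  cross <- as.vector(stats::dist(emb$cell_coords))
  expect_lt(stats::quantile(paired, 0.9), stats::quantile(cross, 0.1))
})

test_that("rank-1 data integrates onto a single latent direction", {
  u <- 1:12
  counts <- outer(c(2, 4, 6, 8, 10, 12, 14, 16, 18, 20), u)
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(paste0("g", 1:10), paste0("c", 1:12))
  sc <- tiny_sc(counts, rep("A", 12))
  sc$norm <- counts + 0
  stc <- counts
  colnames(stc) <- paste0("s", seq_len(ncol(stc)))
  st <- spatial_dataset(stc, cbind(seq_len(12), 0))
  st$norm <- stc + 0
  emb <- integrate_datasets(sc, st, rownames(counts), d = 1)
  expect_equal(emb$d_cca, 1L)
  expect_true(all(abs(abs(emb$cell_coords[, 1]) - 1) < 1e-8))
})

test_that("integration fails informatively with too few shared genes", {
  sc <- normalize_data(small_fixture(seed = 3, n_cells = 30, n_genes = 50,
                                     markers_per_type = 5))
  st <- normalize_data(tiny_st(matrix(1:20, 5, 4,
    dimnames = list(paste0("other", 1:5), NULL))))
  expect_error(integrate_datasets(sc, st, sc$gene_ids), "0 shared")
})

test_that("the 2D projection is deterministic and keeps populations apart", {
  fx <- integration_fixture(seed = 31)
  emb <- integrate_datasets(fx$sc, fx$st, fx$sc$gene_ids, d = 10, seed = 1)
  a <- embed_2d(emb, seed = 5, n_neighbors = 15)
  b <- embed_2d(emb, seed = 5, n_neighbors = 15)
  expect_identical(a$cell_coords, b$cell_coords)
  expect_identical(a$spot_coords, b$spot_coords)

  sil <- cluster::silhouette(as.integer(factor(fx$sc$cell_type)),
                             stats::dist(a$cell_coords))
  expect_gt(mean(sil[, "sil_width"]), 0)
})

test_that("tiny inputs reduce the neighbour count with a warning", {
  sc <- normalize_data(small_fixture(seed = 5, n_cells = 10, n_genes = 40,
                                     n_types = 2, markers_per_type = 5))
  counts <- sc$counts
  colnames(counts) <- paste0("s", seq_len(ncol(counts)))
  st <- normalize_data(spatial_dataset(counts, cbind(seq_len(10), 0)))
  emb <- integrate_datasets(sc, st, sc$gene_ids, d = 5)
  expect_warning(embed_2d(emb, n_neighbors = 50), "n_neighbors reduced")
})

test_that("label transfer picks nearest cells with documented tie-breaks", {
  emb <- structure(list(
    cell_coords = rbind(cA = c(1, 0), cB = c(2, 0)),
    spot_coords = rbind(s1 = c(0, 0))), class = "joint_embedding")
  st <- tiny_st(matrix(1:2, 2, 1))
  st$cluster <- c(s1 = 3L)
  ts <- transfer_labels(emb, st, k = 1)
  expect_equal(ts$cell_id, "cA")
  expect_equal(ts$cluster, 3L)

  # one cell equidistant to two spots of different clusters
  emb2 <- structure(list(
    cell_coords = rbind(cA = c(0, 0)),
    spot_coords = rbind(s2 = c(1, 0), s1 = c(-1, 0))), class = "joint_embedding")
  st2 <- tiny_st(matrix(1:4, 2, 2))
  st2$cluster <- c(s1 = 7L, s2 = 8L)
  ts2 <- transfer_labels(emb2, st2, k = 1)
  expect_equal(ts2$spot_id, "s1")          # lexicographically first spot wins
  expect_equal(ts2$cluster, 7L)

  expect_error(transfer_labels(emb2, st2, k = 5), "exceeds")
})

test_that("the transfer set respects its cardinality bounds", {
  fx <- integration_fixture(seed = 37)
  emb <- integrate_datasets(fx$sc, fx$st, fx$sc$gene_ids, d = 10, seed = 1)
  emb <- embed_2d(emb, seed = 1, n_neighbors = 15)
  for (k in c(1L, 5L)) {
    ts <- transfer_labels(emb, fx$st, k = k)
    expect_lte(nrow(ts), ncol(fx$st$counts) * k)
    expect_lte(nrow(ts), ncol(fx$sc$counts))
    expect_false(anyDuplicated(ts$cell_id) > 0)
  }
})

test_that("the forest separates a linearly separable transfer set", {
  fx <- integration_fixture(seed = 41)
  emb <- integrate_datasets(fx$sc, fx$st, fx$sc$gene_ids, d = 10, seed = 1)
  emb <- embed_2d(emb, seed = 1, n_neighbors = 15)
  ts <- transfer_labels(emb, fx$st, k = 5)
  model <- train_rf(ts, fx$sc, fx$sc$gene_ids, n_trees = 100, seed = 1)
  pred <- predict_clusters(model, fx$sc)
  expect_true(all(pred %in% ts$cluster))   # predictions stay in the label set
  train_pred <- pred[ts$cell_id]
  expect_gte(mean(train_pred == ts$cluster), 0.95)

  pred2 <- predict_clusters(train_rf(ts, fx$sc, fx$sc$gene_ids,
                                     n_trees = 100, seed = 1), fx$sc)
  expect_identical(pred, pred2)            # same seed, same predictions
})

test_that("degenerate and erroneous classifier inputs are handled", {
  fx <- integration_fixture(seed = 43)
  ts <- data.frame(cell_id = fx$sc$cell_ids[1:10],
                   spot_id = "s1", cluster = 0L, dist = 0)
  expect_warning(model <- train_rf(ts, fx$sc, fx$sc$gene_ids, n_trees = 10),
                 "single cluster")
  expect_equal(unique(unname(predict_clusters(model, fx$sc))), 0L)

  ts2 <- ts; ts2$cluster <- rep(0:1, 5)
  model2 <- train_rf(ts2, fx$sc, fx$sc$gene_ids, n_trees = 10, seed = 1)
  other <- tiny_sc(matrix(1L, 2, 1, dimnames = list(c("x1", "x2"), "c1")), "A")
  other <- normalize_data(other)
  expect_error(predict_clusters(model2, other), "lacks")

  # an all-zero cell still receives some valid label
  zc <- fx$sc$counts[, 1:3]
  zc[, 3] <- 0L
  sczero <- suppressWarnings(normalize_data(annotated_sc(zc, fx$sc$cell_type[1:3])))
  pz <- predict_clusters(model2, sczero)
  expect_equal(length(pz), 3L)
  expect_true(all(pz %in% 0:1))
})

test_that("more trees do not hurt held-out accuracy on separable data", {
  fx <- integration_fixture(seed = 47)
  emb <- integrate_datasets(fx$sc, fx$st, fx$sc$gene_ids, d = 10, seed = 1)
  emb <- embed_2d(emb, seed = 1, n_neighbors = 15)
  ts <- transfer_labels(emb, fx$st, k = 5)
  m1 <- train_rf(ts, fx$sc, fx$sc$gene_ids, n_trees = 1, seed = 1)
  m1000 <- train_rf(ts, fx$sc, fx$sc$gene_ids, n_trees = 500, seed = 1)
  p1 <- predict_clusters(m1, fx$sc)[ts$cell_id]
  p1000 <- predict_clusters(m1000, fx$sc)[ts$cell_id]
  expect_gte(mean(p1000 == ts$cluster), mean(p1 == ts$cluster))
})
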