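test_that("type means average the normalized layer within each type", {
  sc <- tiny_sc(matrix(0L, 2, 3, dimnames = list(c("g1", "g2"), c("c1", "c2", "c3"))),
                c("A", "A", "B"))
  sc$norm <- matrix(c(2, 1, 4, 5, 7, 9), 2, 3, dimnames = dimnames(sc$counts))
  Y <- type_means(sc)
  expect_equal(Y["g1", "A"], 3)           # mean of 2 and 4
  expect_equal(unname(Y[, "B"]), c(7, 9)) # single cell: column equals the cell

  perm <- c(3, 1, 2)
  scp <- sc
  scp$counts <- sc$counts[, perm]; scp$norm <- sc$norm[, perm]
  scp$cell_type <- sc$cell_type[perm]
  scp$cell_ids <- sc$cell_ids[perm]
  expect_equal(type_means(scp), Y)
  sc1 <- tiny_sc(matrix(1L, 1, 1), "A")
  sc1$norm <- matrix(1, 1, 1, dimnames = dimnames(sc1$counts))
  expect_error(type_means(sc1), "2 cell types")
})

test_that("fold change matches its closed form, with an epsilon guard", {
  Y <- rbind(equal = c(3, 3, 3), spec = c(4, 1, 1), lone = c(4, 0, 0))
  colnames(Y) <- c("A", "B", "C")
  fc <- fold_change(Y)
  expect_equal(unname(fc["equal", ]), c(1, 1, 1))
  expect_equal(fc["spec", "A"], 4 / 2 * 2)     # = 4.0
  expect_equal(fc["spec", "B"], 1 / 5 * 2)     # = 0.4
  expect_true(is.finite(fc["lone", "A"]))
  expect_equal(fc["lone", "A"], 4 / 1e-9 * 2)
  expect_gt(fc["lone", "A"], max(fc[c("equal", "spec"), ]))
})

test_that("fold change and its tanh-weighted form are scale-invariant", {
  # the weight W is a ratio of medians, so a global rescaling of Y cancels
  # in both FC and FC'
  sc <- small_fixture(seed = 11, n_cells = 80, n_genes = 60,
                      markers_per_type = 10)
  Y <- type_means(normalize_data(sc))
  expect_equal(fold_change(3.7 * Y), fold_change(Y))
  a <- seed_weights(Y, fold_change(Y))$fc_prime
  b <- seed_weights(3.7 * Y, fold_change(3.7 * Y))$fc_prime
  expect_equal(a, b)
})

test_that("tanh expression weights follow the closed form", {
  # gene g1 has per-type median equal to the global median of medians -> W = 1
  Y <- rbind(g1 = c(2, 2, 2), g2 = c(0, 0, 0), g3 = c(40, 40, 40))
  colnames(Y) <- c("A", "B", "C")
  fc <- fold_change(Y)
  sw <- seed_weights(Y, fc, lambda = 0.1)
  expect_equal(unname(sw$w["g1"]), 1)
  expect_equal(unname(sw$fc_prime["g1", ] / fc["g1", ]), rep(tanh(0.1), 3))
  expect_equal(tanh(0.1), 0.0996680, tolerance = 1e-6)
  expect_equal(unname(sw$fc_prime["g2", ]), c(0, 0, 0))  # W = 0 -> tanh(0) = 0
  expect_equal(unname(sw$w["g3"]), 20)
  expect_equal(unname(sw$fc_prime["g3", 1] / fc["g3", 1]), tanh(2))
  expect_equal(tanh(2), 0.9640276, tolerance = 1e-6)

  Yz <- matrix(0, 3, 2, dimnames = list(paste0("g", 1:3), c("A", "B")))
  expect_error(seed_weights(Yz, fold_change(Yz)), "median")
})

test_that("seed selection takes the top genes with lexicographic tie-breaks", {
  fcp <- matrix(c(5, 1, 3), 3, 1, dimnames = list(c("g1", "g2", "g3"), "A"))
  expect_equal(select_seeds(fcp, 2)$A, c("g1", "g3"))

  tie <- matrix(c(2, 2, 1), 3, 1, dimnames = list(c("gB", "gA", "gC"), "A"))
  expect_equal(select_seeds(tie, 2)$A, c("gA", "gB"))

  expect_warning(out <- select_seeds(fcp, 10), "all")
  expect_equal(length(out$A), 3L)

  # one gene can seed two types when it dominates both columns
  both <- matrix(c(9, 1, 9, 2), 2, 2,
                 dimnames = list(c("g1", "g2"), c("A", "B")))
  seeds <- select_seeds(both, 1)
  expect_equal(seeds$A, "g1")
  expect_equal(seeds$B, "g1")
})

test_that("signal matrix zeroes constant genes and preserves correlation structure", {
  set.seed(2)
  base <- rpois(30, 5)
  counts <- rbind(g1 = base, g2 = base * 2L,    # perfectly correlated pair
                  g3 = rep(4L, 30),             # constant
                  g4 = rpois(30, 5), g5 = rpois(30, 3), g6 = rpois(30, 2))
  sc <- tiny_sc(counts, rep(c("A", "B"), 15))
  sc$norm <- counts + 0                          # identity layer: exact algebra
  sig <- signal_matrix(sc, var_explained = 1, max_components = 30)
  expect_equal(unname(sig$Q[, "g3"]), rep(0, sig$t))
  expect_equal(sig$zero_var, "g3")
  q1 <- sig$Q[, "g1"]; q2 <- sig$Q[, "g2"]
  expect_equal(sum(q1 * q2) / sqrt(sum(q1^2) * sum(q2^2)), 1)

  # at full rank, Q reproduces the z-scored cross-product exactly
  mu <- rowMeans(sc$norm); sd <- sqrt(rowMeans((sc$norm - mu)^2)); sd[sd == 0] <- 1
  z <- (sc$norm - mu) / sd
  expect_equal(unname(crossprod(sig$Q)), unname(tcrossprod(z)), tolerance = 1e-8)
})

test_that("artanh agrees with its logarithmic closed form", {
  r <- seq(-0.999, 0.999, length.out = 201)
  expect_equal(atanh(r), 0.5 * (log(1 + r) - log(1 - r)), tolerance = 1e-12)
  expect_equal(atanh(0.9), 0.5 * log(1.9 / 0.1))
  expect_equal(atanh(0.9), 1.47222, tolerance = 1e-5)
})

test_that("co-expression expansion keeps seeds and respects the p cutoff", {
  set.seed(4)
  t_comp <- 12L
  seed_col <- rnorm(t_comp)
  Q <- cbind(gSeed = seed_col,                           # t x m orientation
             gCor = seed_col + rnorm(t_comp, 0, 0.05),   # strongly correlated
             gOrth = rnorm(t_comp))                      # independent
  sig <- list(Q = Q, t = t_comp, zero_var = character(0))
  fs <- coexpression_expand(sig, list(A = "gSeed"), p_cutoff = 0.01)
  expect_true("gSeed" %in% fs$per_type$A)
  expect_true("gCor" %in% fs$per_type$A)

  # r = 0 gives z' = 0 and p = 1: never assigned
  Q0 <- rbind(c(1, -1, 1, -1, 1, -1, 1, -1), c(1, 1, -1, -1, 1, 1, -1, -1))
  Q0 <- t(Q0); colnames(Q0) <- c("gSeed", "gFlat")
  sig0 <- list(Q = Q0, t = 8L, zero_var = character(0))
  fs0 <- coexpression_expand(sig0, list(A = "gSeed"), p_cutoff = 0.999)
  expect_false("gFlat" %in% fs0$per_type$A)

  expect_error(coexpression_expand(list(Q = Q, t = 3L, zero_var = character(0)),
                                   list(A = "gSeed")), "t > 3")
})

test_that("the feature list grows monotonically with the p cutoff", {
  sc <- normalize_data(small_fixture(seed = 13))
  cfg <- spot_config()
  sig <- signal_matrix(sc)
  seeds <- select_seeds(seed_weights(type_means(sc),
                                     fold_change(type_means(sc)))$fc_prime,
                        cfg$seed_num)
  sizes <- vapply(c(1e-4, 1e-2, 0.1),
                  function(p) length(coexpression_expand(sig, seeds, p)$G),
                  numeric(1))
  expect_true(all(diff(sizes) >= 0))
})

test_that("planted markers are recovered by their generating type", {
  sc <- normalize_data(small_fixture(seed = 17))
  fs <- select_features(sc, spot_config(seed_num = 15))
  markers <- attr(sc, "markers")
  for (ty in names(markers)) {
    expect_true(all(markers[[ty]] %in% fs$per_type[[ty]]),
                label = paste("markers of", ty, "recovered"))
  }
})
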