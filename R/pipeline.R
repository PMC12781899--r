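#' Run the full single-cell-to-spot mapping pipeline
#'
#' Orchestrates normalization, spot clustering, feature-gene selection,
#' SC/ST integration and 2D embedding, label transfer, random-forest
#' cluster prediction, per-cluster cosine similarity, per-spot cell-count
#' estimation, and globally optimal assignment.
#'
#' @param sc An `annotated_sc` (raw counts; normalized internally).
#' @param st A `spatial_dataset` (raw counts + coordinates).
#' @param config A [spot_config()].
#' @param outdir Optional directory: assignment TSV, proportions CSV,
#'   feature audit TSVs, config snapshot and run log are written there.
#' @return List of class `map_result`: `assignment` (a `cell_assignment`),
#'   `proportions`, `features`, `counts`, `cell_cluster`, `st` (clustered),
#'   `manifest` (stage timings, seeds, warnings, file paths).
#' @export
run_map <- function(sc, st, config = spot_config(), outdir = NULL) {
  manifest <- list(config = config[setdiff(names(config), "norm_fun")],
                   seeds = config$rng_seed, timings = list(),
                   warnings = character(0), files = character(0))
  log_msg <- function(...) message("[spotmatch] ", ...)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- withCallingHandlers(expr, warning = function(w) {
      manifest$warnings <<- c(manifest$warnings, paste0(name, ": ", conditionMessage(w)))
      invokeRestart("muffleWarning")
    })
    manifest$timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    log_msg(name, " done (", manifest$timings[[name]], "s)")
    res
  }

  sc <- stage("normalize_sc", normalize_data(sc, norm_fun = config$norm_fun))
  st <- stage("normalize_st", normalize_data(st, norm_fun = config$norm_fun))
  st <- stage("cluster_spots", cluster_spots(
    st, resolution = config$cluster_resolution, n_pcs = config$n_pcs,
    seed = config$rng_seed))
  features <- stage("select_features", select_features(sc, config))
  emb <- stage("integrate", integrate_datasets(
    sc, st, features$G, d = config$cca_dim, seed = config$rng_seed))
  emb <- stage("embed_2d", embed_2d(
    emb, seed = config$rng_seed, n_neighbors = config$umap_neighbors,
    min_dist = config$umap_min_dist))
  transfer <- stage("transfer_labels", transfer_labels(emb, st, k = config$knn_k))
  model <- stage("train_rf", train_rf(
    transfer, sc, features$G, n_trees = config$n_trees, seed = config$rng_seed))
  if (!is.null(model$oob)) log_msg("random forest OOB error: ", round(model$oob, 4))
  cell_cluster <- stage("predict_clusters", predict_clusters(model, sc))
  stable <- stage("stable_genes", stable_genes(st, config$var_threshold))
  counts <- stage("estimate_counts", estimate_counts(
    st, stable, mean_cell_num = config$mean_cell_num))

  genes <- emb$genes
  scn <- .dense(sc$norm)[genes, , drop = FALSE]
  stn <- .dense(st$norm)[genes, , drop = FALSE]
  clusters <- sort(unique(st$cluster))
  per_cluster <- stage("assign", {
    out <- list()
    for (z in clusters) {
      spots_z <- st$spot_ids[st$cluster == z]
      cells_z <- names(cell_cluster)[cell_cluster == z]
      if (length(cells_z) == 0) {
        warning("cluster ", z, ": no cells predicted; its ", length(spots_z),
                " spot(s) stay empty")
        next
      }
      simi <- cosine_similarity(scn[, cells_z, drop = FALSE],
                                stn[, spots_z, drop = FALSE])
      sol <- solve_assignment(expand_subspots(simi, counts))
      log_msg("cluster ", z, ": ", nrow(sol$pairs), " pairs, cost ",
              round(sol$cost, 2), ", ", sum(sol$pairs$duplicated),
              " duplicated, ", length(sol$unassigned_cells), " unassigned")
      out[[as.character(z)]] <- sol
    }
    out
  })
  assignment <- stage("aggregate", aggregate_assignments(
    per_cluster, st, sc, jitter_radius = config$jitter_radius,
    seed = config$rng_seed))

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    files <- write_outputs(assignment, assignment$proportions, outdir)
    files <- c(files, export_features(features, outdir))
    cfg <- file.path(outdir, "config.yaml")
    write_config(config, cfg)
    manifest$files <- c(files, config = cfg)
    writeLines(c(paste("seed:", config$rng_seed),
                 paste(names(manifest$timings),
                       unlist(manifest$timings), sep = ": "),
                 manifest$warnings),
               file.path(outdir, "run_log.txt"))
  }
  structure(list(assignment = assignment, proportions = assignment$proportions,
                 features = features, counts = counts,
                 cell_cluster = cell_cluster, st = st, manifest = manifest),
            class = "map_result")
}

#' @export
print.map_result <- function(x, ...) {
  print(x$assignment)
  invisible(x)
}

#' Benchmark a predicted composition against ground truth
#'
#' @param truth,pred Spots x types composition matrices on the same spots.
#' @param base JS logarithm base.
#' @return A `metrics_report` (see [benchmark_composition()]).
#' @export
run_benchmark <- function(truth, pred, base = exp(1)) {
  missing <- setdiff(rownames(truth), rownames(pred))
  if (length(missing) > 0) {
    stop("prediction lacks ", length(missing), " spot(s), e.g. ",
         paste(utils::head(missing, 3), collapse = ", "))
  }
  benchmark_composition(truth, pred[rownames(truth), colnames(truth)], base)
}

#' Generate and write a paired synthetic SC/ST fixture
#'
#' @param spec A [generator_spec()].
#' @param outdir Output directory; SC counts are written as an MTX triplet
#'   with an annotation TSV, ST counts as MTX with a coordinate CSV, and
#'   the truth as TSV.
#' @param n_spots,lambda,perturbation,type_bias Passed to
#'   [simulate_st_poisson()].
#' @return Invisibly, list with `sc`, `sim`, and the manifest of written
#'   files.
#' @export
run_simulate <- function(spec = generator_spec(), outdir, n_spots = 200L,
                         lambda = 5, perturbation = 0.01, type_bias = NULL) {
  sc <- make_sc(spec)
  sim <- simulate_st_poisson(sc, n_spots = n_spots, lambda = lambda,
                             perturbation = perturbation, seed = spec$seed,
                             type_bias = type_bias)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  scdir <- file.path(outdir, "sc"); stdir <- file.path(outdir, "st")
  write_mtx(sc$counts, scdir)
  utils::write.table(data.frame(cell_id = sc$cell_ids, cell_type = sc$cell_type),
                     file.path(outdir, "annotations.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_mtx(sim$st$counts, stdir)
  utils::write.csv(data.frame(spot_id = sim$st$spot_ids,
                              x = sim$st$coords[, 1], y = sim$st$coords[, 2]),
                   file.path(outdir, "coords.csv"), row.names = FALSE)
  truth <- data.frame(spot_id = names(sim$truth$n_true),
                      n_true = sim$truth$n_true,
                      sim$truth$proportions, check.names = FALSE)
  utils::write.table(truth, file.path(outdir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  files <- c(sc = scdir, st = stdir,
             annotations = file.path(outdir, "annotations.tsv"),
             coords = file.path(outdir, "coords.csv"),
             truth = file.path(outdir, "truth.tsv"))
  invisible(list(sc = sc, sim = sim, files = files))
}
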