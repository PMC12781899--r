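#' Read single-cell expression data with cell-type annotations
#'
#' Supported layouts: 10x-style MTX triplet (`matrix.mtx[.gz]` +
#' `features.tsv[.gz]` + `barcodes.tsv[.gz]` in a directory), a dense
#' CSV/TSV matrix (genes as rows), or a 10x CellRanger-style HDF5 file.
#' Duplicate gene symbols are collapsed by summation.
#'
#' @param path Directory (mtx) or file (csv/h5).
#' @param annotations Path to a TSV with columns `cell_id`, `cell_type`, or a
#'   named character vector of labels.
#' @param format One of `"mtx"`, `"csv"`, `"h5"`; guessed from `path` when
#'   missing.
#' @return An [annotated_sc()] object.
#' @export
read_sc <- function(path, annotations, format = c("auto", "mtx", "csv", "h5")) {
  format <- match.arg(format)
  counts <- .read_matrix_any(path, format)
  if (is.character(annotations) && length(annotations) == 1 && file.exists(annotations)) {
    ann <- utils::read.delim(annotations, sep = "\t", stringsAsFactors = FALSE)
    if (!all(c("cell_id", "cell_type") %in% names(ann))) {
      stop("annotation file must contain columns 'cell_id' and 'cell_type'; found: ",
           paste(names(ann), collapse = ", "))
    }
    labels <- stats::setNames(as.character(ann$cell_type), ann$cell_id)
  } else if (!is.null(names(annotations)) || length(annotations) == ncol(counts)) {
    labels <- annotations
  } else {
    stop("annotations must be a TSV path or a per-cell label vector")
  }
  annotated_sc(counts, labels)
}

#' Read spatial transcriptomics data
#'
#' Same matrix formats as [read_sc()]; coordinates come from a CSV with
#' columns `spot_id`, `x`, `y`.
#'
#' @param path Matrix location (see [read_sc()]).
#' @param coords Path to the coordinate CSV, or a matrix/data.frame.
#' @param format Matrix format, see [read_sc()].
#' @return A [spatial_dataset()] object.
#' @export
read_st <- function(path, coords, format = c("auto", "mtx", "csv", "h5")) {
  format <- match.arg(format)
  counts <- .read_matrix_any(path, format)
  if (is.character(coords) && length(coords) == 1) {
    cc <- utils::read.csv(coords, stringsAsFactors = FALSE)
    if (!all(c("spot_id", "x", "y") %in% names(cc))) {
      stop("coordinate file must contain columns 'spot_id', 'x', 'y'")
    }
    coords <- as.matrix(cc[, c("x", "y")])
    rownames(coords) <- cc$spot_id
  }
  spatial_dataset(counts, coords)
}

.read_matrix_any <- function(path, format = "auto") {
  if (format == "auto") {
    format <- if (dir.exists(path)) "mtx"
      else if (grepl("\\.h5$", path)) "h5"
      else "csv"
  }
  switch(format,
    mtx = .read_mtx_dir(path),
    csv = .read_dense(path),
    h5  = .read_10x_h5(path),
    stop("unknown format: ", format))
}

.find_one <- function(dir, stem) {
  hits <- list.files(dir, pattern = paste0("^", stem, "(\\.gz)?$"), full.names = TRUE)
  if (length(hits) == 0) stop("no ", stem, " found in ", dir)
  hits[1]
}

.read_mtx_dir <- function(dir) {
  mtx <- .find_one(dir, "matrix\\.mtx")
  feats <- tryCatch(.find_one(dir, "features\\.tsv"),
                    error = function(e) .find_one(dir, "genes\\.tsv"))
  bars <- .find_one(dir, "barcodes\\.tsv")
  m <- Matrix::readMM(mtx)
  ft <- utils::read.delim(feats, header = FALSE, stringsAsFactors = FALSE)
  bc <- utils::read.delim(bars, header = FALSE, stringsAsFactors = FALSE)
  # 10x features.tsv carries id + symbol; use the symbol column when present
  rownames(m) <- if (ncol(ft) >= 2) ft[[2]] else ft[[1]]
  colnames(m) <- bc[[1]]
  methods::as(m, "CsparseMatrix")
}

# row.names handled manually: duplicated gene symbols are legal on input
# (collapsed downstream by summation).
.read_dense <- function(path) {
  sep <- if (grepl("\\.tsv(\\.gz)?$", path)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  m
}

.read_10x_h5 <- function(path) {
  if (!requireNamespace("rhdf5", quietly = TRUE)) {
    stop("reading .h5 requires the rhdf5 package")
  }
  root <- rhdf5::h5ls(path, recursive = FALSE)$name[1]
  g <- function(x) rhdf5::h5read(path, paste0(root, "/", x))
  shape <- as.integer(g("shape"))
  m <- Matrix::sparseMatrix(i = as.integer(g("indices")) + 1L,
                            p = as.integer(g("indptr")),
                            x = as.numeric(g("data")),
                            dims = shape)
  feat <- tryCatch(as.character(g("features/name")),
                   error = function(e) as.character(g("genes")))
  rownames(m) <- feat
  colnames(m) <- as.character(g("barcodes"))
  m
}

#' Write a count matrix as a 10x-style MTX triplet
#'
#' @param counts genes x columns matrix with dimnames.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_mtx <- function(counts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  utils::write.table(data.frame(id = rownames(m), name = rownames(m),
                                type = "Gene Expression"),
                     file.path(dir, "features.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(colnames(m), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Write mapping outputs
#'
#' Writes the assignment table (TSV: `cell_id`, `spot_id`, `sub_spot_index`,
#' `cell_type`, `x`, `y`) and the per-spot cell-type proportion matrix (CSV,
#' rows summing to 1 for non-empty spots).
#'
#' @param assignment A `cell_assignment` (see [aggregate_assignments()]).
#' @param proportions Spots x types matrix.
#' @param outdir Output directory.
#' @return Named character vector of written paths, invisibly.
#' @export
write_outputs <- function(assignment, proportions, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  apath <- file.path(outdir, "assignment.tsv")
  ppath <- file.path(outdir, "proportions.csv")
  df <- assignment$pairs[, c("cell_id", "spot_id", "sub_spot_index",
                             "cell_type", "x", "y")]
  utils::write.table(df, apath, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.csv(as.data.frame(proportions), ppath, quote = FALSE)
  invisible(c(assignment = apath, proportions = ppath))
}

#' Read/write a flat key-value configuration file (YAML)
#'
#' @param path YAML file mirroring [spot_config()] fields.
#' @return A `spot_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(spot_config, vals)
}

#' @rdname read_config
#' @param config A `spot_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config[setdiff(names(config), "norm_fun")], path)
  invisible(path)
}
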