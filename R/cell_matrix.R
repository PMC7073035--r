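#' Single-cell UMI count container
#'
#' A `cell_matrix` holds a sparse cells-by-genes raw UMI count matrix together
#' with per-cell metadata and optional derived layers (the normalized/log
#' layer). Raw counts are never mutated by downstream steps: pathway scores are
#' computed on raw counts, while HVG selection, PCA, clustering and marker
#' ranking use the log layer.
#'
#' @param counts Cells x genes matrix of non-negative integers (dense or
#'   sparse; coerced to `dgCMatrix`). Rownames are cell barcodes, colnames
#'   gene symbols.
#' @param obs Optional per-cell metadata data frame with a `barcode` column
#'   (one row per cell, same order as `counts`).
#' @param batch Optional per-cell batch labels (recycled if length 1).
#'
#' @return A `cell_matrix` object: list with `counts` (dgCMatrix), `obs`
#'   (tibble) and `layers` (named list of matrices conformable with `counts`).
#' @export
#' @examples
#' m <- cell_matrix(matrix(rpois(20, 2), 4, 5,
#'   dimnames = list(paste0("c", 1:4), paste0("g", 1:5))))
cell_matrix <- function(counts, obs = NULL, batch = NULL) {
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"),
                                    "generalMatrix"), "CsparseMatrix")
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("cell%04d", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("gene%04d", seq_len(ncol(counts)))
  }
  v <- counts@x
  if (any(v < 0)) abort("counts must be non-negative")
  if (any(v != round(v))) abort("counts must be integers (raw UMIs)")
  if (is.null(obs)) obs <- tibble(barcode = rownames(counts))
  obs <- as_tibble(obs)
  if (!"barcode" %in% names(obs)) obs <- dplyr::bind_cols(tibble(barcode = rownames(counts)), obs)
  if (nrow(obs) != nrow(counts)) abort("obs rows must match number of cells")
  if (!identical(obs$barcode, rownames(counts))) {
    abort("obs$barcode must equal rownames(counts) in order")
  }
  if (!is.null(batch)) obs$batch <- rep_len(as.character(batch), nrow(counts))
  if (!"batch" %in% names(obs)) obs$batch <- "batch1"
  structure(list(counts = counts, obs = obs, layers = list()),
            class = "cell_matrix")
}

#' @export
print.cell_matrix <- function(x, ...) {
  cat(sprintf("<cell_matrix> %d cells x %d genes; layers: %s\n",
              nrow(x$counts), ncol(x$counts),
              if (length(x$layers)) paste(names(x$layers), collapse = ", ") else "none"))
  cat(sprintf("  obs: %s\n", paste(names(x$obs), collapse = ", ")))
  invisible(x)
}

#' @export
dim.cell_matrix <- function(x) dim(x$counts)

n_cells <- function(m) nrow(m$counts)

subset_cells <- function(m, keep) {
  m$counts <- m$counts[keep, , drop = FALSE]
  m$obs <- m$obs[keep, , drop = FALSE]
  m$layers <- lapply(m$layers, function(l) l[keep, , drop = FALSE])
  m
}

# ---- 10x-style IO -----------------------------------------------------------

#' Read a 10x-style MTX directory
#'
#' Expects `matrix.mtx` (genes x cells, Matrix Market), `barcodes.tsv` and
#' either `features.tsv` (v3) or `genes.tsv` (v2); the second column of the
#' feature table is used as the gene symbol when present.
#'
#' @param dir Directory containing the three files.
#' @param batch Batch label recorded for all cells (default: directory name).
#' @return A [cell_matrix()] (cells x genes).
#' @export
read_mtx_dir <- function(dir, batch = basename(normalizePath(dir))) {
  mtx <- file.path(dir, "matrix.mtx")
  if (!file.exists(mtx)) abort(sprintf("no matrix.mtx in %s", dir))
  counts <- Matrix::t(Matrix::readMM(mtx))
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  feat_file <- file.path(dir, "features.tsv")
  if (!file.exists(feat_file)) feat_file <- file.path(dir, "genes.tsv")
  if (!file.exists(feat_file)) abort(sprintf("no features.tsv/genes.tsv in %s", dir))
  feats <- read.delim(feat_file, header = FALSE, stringsAsFactors = FALSE)
  symbols <- if (ncol(feats) >= 2) feats[[2]] else feats[[1]]
  symbols <- make.unique(symbols)
  if (length(barcodes) != nrow(counts) || length(symbols) != ncol(counts)) {
    abort("barcode/feature table sizes do not match the matrix")
  }
  dimnames(counts) <- list(barcodes, symbols)
  cell_matrix(counts, batch = batch)
}

#' Write a cell_matrix as a 10x-style MTX directory
#'
#' Emits `matrix.mtx` (genes x cells), `barcodes.tsv` and `features.tsv`
#' (feature id and symbol both set to the gene symbol).
#'
#' @param m A [cell_matrix()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_mtx_dir <- function(m, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(Matrix::t(m$counts), file.path(dir, "matrix.mtx"))
  writeLines(rownames(m$counts), file.path(dir, "barcodes.tsv"))
  write.table(data.frame(colnames(m$counts), colnames(m$counts), "Gene Expression"),
              file.path(dir, "features.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

#' Concatenate cell matrices across batches
#'
#' @param ... `cell_matrix` objects (or a single list of them) sharing the
#'   same gene panel.
#' @return A combined [cell_matrix()]; derived layers are dropped.
#' @export
concat_cell_matrices <- function(...) {
  ms <- list(...)
  if (length(ms) == 1L && !inherits(ms[[1]], "cell_matrix")) ms <- ms[[1]]
  genes <- colnames(ms[[1]]$counts)
  for (m in ms) {
    if (!identical(colnames(m$counts), genes)) abort("gene panels differ between batches")
  }
  counts <- do.call(rbind, lapply(ms, `[[`, "counts"))
  rownames(counts) <- make.unique(unlist(lapply(ms, function(m) rownames(m$counts))))
  obs <- dplyr::bind_rows(lapply(ms, `[[`, "obs"))
  obs$barcode <- rownames(counts)
  cell_matrix(counts, obs = obs)
}

# ---- QC ---------------------------------------------------------------------

#' Compute per-cell QC metrics
#'
#' Fills `total_umi`, `n_genes` and `mito_fraction` (UMIs on genes whose
#' symbol starts with a mitochondrial prefix, divided by total UMIs) in the
#' cell metadata. Cells with zero total UMIs get `mito_fraction = 0` and are
#' flagged in `zero_umi`.
#'
#' @param m A [cell_matrix()].
#' @param mito_prefixes Symbol prefixes identifying mitochondrial genes.
#' @return `m` with QC columns filled in `m$obs`.
#' @export
compute_qc_metrics <- function(m, mito_prefixes = c("MT-", "mt-")) {
  stopifnot(inherits(m, "cell_matrix"))
  tot <- Matrix::rowSums(m$counts)
  ngene <- Matrix::rowSums(m$counts > 0)
  pat <- paste0("^(", paste(vapply(mito_prefixes, .escape_rx, ""), collapse = "|"), ")")
  mito <- grepl(pat, colnames(m$counts))
  mito_umi <- if (any(mito)) Matrix::rowSums(m$counts[, mito, drop = FALSE]) else rep(0, n_cells(m))
  frac <- ifelse(tot > 0, mito_umi / tot, 0)
  m$obs$total_umi <- as.numeric(tot)
  m$obs$n_genes <- as.integer(ngene)
  m$obs$mito_fraction <- as.numeric(frac)
  m$obs$zero_umi <- tot == 0
  m
}

.escape_rx <- function(x) gsub("([][{}()+*^$|\\\\?.-])", "\\\\\\1", x)

#' QC thresholds and presets
#'
#' Boundary semantics follow the protocol text literally: `min_umi` and
#' `max_umi` are exclusive ("more than"/"fewer than"), the gene-count window
#' is inclusive ("between"), and `max_mito_fraction` is exclusive. The
#' `e15_mouse` preset keeps cells with more than 2000 UMIs and 400-3500 genes;
#' the `organoid` preset keeps cells with 500-7000 genes, fewer than 20,000
#' UMIs and a mitochondrial fraction below 0.001 (the printed 0.1%; unusually
#' strict, kept as a parameter).
#'
#' @param min_umi Exclusive lower UMI bound.
#' @param min_genes,max_genes Inclusive detected-gene window.
#' @param max_umi Exclusive upper UMI bound (`Inf` to disable).
#' @param max_mito_fraction Exclusive mitochondrial-fraction ceiling
#'   (`Inf` to disable).
#' @return A `qc_thresholds` object.
#' @export
#' @examples
#' qc_preset("e15_mouse")
qc_thresholds <- function(min_umi = 0, min_genes = 0, max_genes = Inf,
                          max_umi = Inf, max_mito_fraction = Inf) {
  stopifnot(min_genes <= max_genes, min_umi >= 0, min_genes >= 0)
  structure(list(min_umi = min_umi, min_genes = min_genes, max_genes = max_genes,
                 max_umi = max_umi, max_mito_fraction = max_mito_fraction),
            class = "qc_thresholds")
}

#' @rdname qc_thresholds
#' @param name Preset name: `"e15_mouse"` or `"organoid"`.
#' @export
qc_preset <- function(name) {
  switch(match.arg(name, c("e15_mouse", "organoid")),
    e15_mouse = qc_thresholds(min_umi = 2000, min_genes = 400, max_genes = 3500),
    organoid  = qc_thresholds(min_genes = 500, max_genes = 7000,
                              max_umi = 20000, max_mito_fraction = 0.001)
  )
}

#' Filter cells on QC thresholds
#'
#' Retains cells with `total_umi > min_umi`, `min_genes <= n_genes <=
#' max_genes`, `total_umi < max_umi` and `mito_fraction < max_mito_fraction`.
#' Per-criterion removal counts are reported and attached as the `qc_log`
#' attribute. Filtering is idempotent.
#'
#' @param m A [cell_matrix()] with QC metrics computed (see
#'   [compute_qc_metrics()]; called automatically if missing).
#' @param thresholds A [qc_thresholds()] or preset name.
#' @return The filtered [cell_matrix()].
#' @export
filter_cells <- function(m, thresholds) {
  if (is.character(thresholds)) thresholds <- qc_preset(thresholds)
  stopifnot(inherits(m, "cell_matrix"), inherits(thresholds, "qc_thresholds"))
  if (!all(c("total_umi", "n_genes", "mito_fraction") %in% names(m$obs))) {
    m <- compute_qc_metrics(m)
  }
  o <- m$obs
  crit <- list(
    min_umi  = o$total_umi > thresholds$min_umi,
    genes    = o$n_genes >= thresholds$min_genes & o$n_genes <= thresholds$max_genes,
    max_umi  = o$total_umi < thresholds$max_umi,
    mito     = o$mito_fraction < thresholds$max_mito_fraction
  )
  keep <- Reduce(`&`, crit)
  removed <- vapply(crit, function(x) sum(!x), 0L)
  log <- tibble(criterion = names(removed), removed = as.integer(removed))
  inform(sprintf("filter_cells: kept %d/%d cells (removed: %s)",
                 sum(keep), length(keep),
                 paste(sprintf("%s=%d", log$criterion, log$removed), collapse = ", ")))
  if (!any(keep)) warn("filter_cells: no cells pass the thresholds")
  out <- subset_cells(m, keep)
  attr(out, "qc_log") <- log
  out
}

# ---- normalization ----------------------------------------------------------

#' Library-size normalize and log-transform
#'
#' Scales each cell's counts to `target_sum` total, then applies natural
#' `log1p`, storing the result as the `lognorm` layer. Raw counts are left
#' untouched (pathway scoring uses raw counts). Zero-count cells stay all-zero
#' and are flagged in `obs$zero_umi`.
#'
#' @param m A [cell_matrix()].
#' @param target_sum Per-cell total after scaling (default 10,000).
#' @return `m` with a `lognorm` layer added.
#' @export
normalize_log <- function(m, target_sum = 1e4) {
  stopifnot(inherits(m, "cell_matrix"), target_sum > 0)
  tot <- Matrix::rowSums(m$counts)
  scale <- ifelse(tot > 0, target_sum / tot, 0)
  norm <- Matrix::Diagonal(x = scale) %*% m$counts
  norm@x <- log1p(norm@x)
  dimnames(norm) <- dimnames(m$counts)
  m$layers$lognorm <- methods::as(norm, "CsparseMatrix")
  m$obs$zero_umi <- tot == 0
  m
}

.log_layer <- function(m) {
  if (is.null(m$layers$lognorm)) abort("log layer missing: run normalize_log() first")
  m$layers$lognorm
}
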