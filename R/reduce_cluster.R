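#' Select highly variable genes common to all batches
#'
#' Per batch, genes are ranked by normalized dispersion of the log layer:
#' dispersion = variance/mean, standardized (z-score) within 20 quantile bins
#' of the gene mean. With several batches the default result is the
#' intersection of the per-batch top-`n_per_batch` lists; when `n_target` is
#' given, the `n_target` genes with the best worst-case (maximum) rank across
#' batches are returned instead.
#'
#' @param m A [cell_matrix()] with a log layer and batch labels.
#' @param n_per_batch Size of each per-batch top list (default 1000).
#' @param n_target Optional target size for the combined list.
#' @return Character vector of selected gene symbols.
#' @export
select_common_hvg <- function(m, n_per_batch = 1000, n_target = NULL) {
  x <- .log_layer(m)
  batches <- split(seq_len(n_cells(m)), m$obs$batch)
  ranks <- vapply(batches, function(idx) {
    .hvg_rank(x[idx, , drop = FALSE])
  }, numeric(ncol(x)))
  rownames(ranks) <- colnames(x)
  if (is.null(n_target)) {
    tops <- apply(ranks, 2, function(r) names(sort(r))[seq_len(min(n_per_batch, length(r)))],
                  simplify = FALSE)
    out <- Reduce(intersect, tops)
  } else {
    worst <- apply(ranks, 1, max)
    out <- names(sort(worst))[seq_len(min(n_target, length(worst)))]
  }
  # preserve panel order for determinism
  colnames(x)[colnames(x) %in% out]
}

# rank genes (1 = most variable) by bin-standardized dispersion; zero-variance
# genes are pushed to the bottom
.hvg_rank <- function(x) {
  mu <- Matrix::colSums(x) / nrow(x)
  ex2 <- Matrix::colSums(x^2) / nrow(x)
  v <- (ex2 - mu^2) * nrow(x) / max(1, nrow(x) - 1)
  disp <- ifelse(mu > 0, v / mu, 0)
  # bin count scales down for small panels so bins hold enough genes to
  # standardize against
  nb <- max(1L, min(20L, ncol(x) %/% 10L))
  br <- unique(quantile(mu, probs = seq(0, 1, length.out = nb + 1), names = FALSE))
  bin <- cut(mu, breaks = br, include.lowest = TRUE, labels = FALSE)
  z <- disp
  # floor the bin sd at a fraction of the global spread: a near-homogeneous
  # bin must not turn noise into large z-scores
  floor_sd <- 0.1 * sd(disp)
  for (b in unique(bin)) {
    i <- which(bin == b)
    s <- max(sd(disp[i]), floor_sd, na.rm = TRUE)
    z[i] <- if (is.na(s) || s == 0) 0 else (disp[i] - mean(disp[i])) / s
  }
  z[v == 0] <- -Inf
  r <- rank(-z, ties.method = "first")
  names(r) <- colnames(x)
  r
}

#' PCA embedding of the log layer
#'
#' Centered (not scaled) principal components of the log layer restricted to
#' the given genes. Components come out ordered by decreasing explained
#' variance.
#'
#' @param m A [cell_matrix()] with a log layer.
#' @param genes Genes to use (default: all).
#' @param n_pcs Number of components (clipped to `min(cells, genes)` with a
#'   warning if too large).
#' @return A `dsb_pca` object: list with `coords` (cells x PCs matrix,
#'   rownames = barcodes) and `var_explained` (fraction per component).
#' @export
embed_pca <- function(m, genes = NULL, n_pcs = 50) {
  x <- .log_layer(m)
  if (!is.null(genes)) {
    missing <- setdiff(genes, colnames(x))
    if (length(missing)) abort(sprintf("genes not in panel: %s",
                                       paste(head(missing, 5), collapse = ", ")))
    x <- x[, genes, drop = FALSE]
  }
  max_pcs <- min(nrow(x) - 1L, ncol(x))
  if (n_pcs > max_pcs) {
    warn(sprintf("n_pcs clipped from %d to %d", n_pcs, max_pcs))
    n_pcs <- max_pcs
  }
  p <- prcomp(as.matrix(x), center = TRUE, scale. = FALSE, rank. = n_pcs)
  coords <- p$x[, seq_len(n_pcs), drop = FALSE]
  rownames(coords) <- rownames(x)
  structure(list(coords = coords,
                 var_explained = (p$sdev^2 / sum(p$sdev^2))[seq_len(n_pcs)]),
            class = "dsb_pca")
}

#' @export
print.dsb_pca <- function(x, ...) {
  cat(sprintf("<dsb_pca> %d cells x %d PCs; PC1 %.1f%% variance\n",
              nrow(x$coords), ncol(x$coords), 100 * x$var_explained[1]))
  invisible(x)
}

#' @export
tidy.dsb_pca <- function(x, ...) {
  dplyr::bind_cols(tibble(barcode = rownames(x$coords)),
                   as_tibble(x$coords, .name_repair = "minimal"))
}

.pca_coords <- function(coords) {
  if (inherits(coords, "dsb_pca")) coords$coords else as.matrix(coords)
}

#' k-nearest-neighbor graph on an embedding
#'
#' Connects each cell to its `k` nearest Euclidean neighbors, symmetrized by
#' union, with edge weight `1/(1 + distance)`. Distance ties are broken
#' deterministically by cell index.
#'
#' @param coords A [embed_pca()] result or a cells x dims matrix.
#' @param k Neighbor count (must be < number of cells).
#' @return A weighted undirected [igraph::graph] with vertex names set to the
#'   cell barcodes.
#' @export
knn_graph <- function(coords, k = 15) {
  x <- .pca_coords(coords)
  n <- nrow(x)
  if (k >= n) abort("k must be smaller than the number of cells")
  d <- as.matrix(dist(x))
  nb <- .knn_indices(d, k)
  ii <- rep(seq_len(n), each = k)
  jj <- as.vector(t(nb))
  w <- 1 / (1 + d[cbind(ii, jj)])
  a <- Matrix::sparseMatrix(i = ii, j = jj, x = w, dims = c(n, n))
  a <- pmax(a, Matrix::t(a))  # union symmetrization, keep weight
  g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected", weighted = TRUE)
  igraph::V(g)$name <- rownames(x) %||% as.character(seq_len(n))
  g
}

# k nearest neighbors per row of a distance matrix, excluding self,
# ties broken by index
.knn_indices <- function(d, k) {
  n <- nrow(d)
  t(vapply(seq_len(n), function(i) {
    ord <- order(d[i, ], seq_len(n))
    ord <- ord[ord != i]
    ord[seq_len(k)]
  }, integer(k)))
}

#' Modularity community detection on a cell graph
#'
#' One configurable implementation with an algorithm switch: `"louvain"`
#' (multi-level modularity) or `"leiden"` (modularity objective). Deterministic
#' given `seed`.
#'
#' @param g Graph from [knn_graph()].
#' @param resolution Resolution parameter (default 1).
#' @param seed Integer seed fixing the partition.
#' @param algorithm `"louvain"` or `"leiden"`.
#' @return Tibble with `barcode` and `cluster` (factor, labels "0", "1", ...
#'   ordered by decreasing cluster size).
#' @export
cluster_graph <- function(g, resolution = 1, seed = 0,
                          algorithm = c("louvain", "leiden")) {
  algorithm <- match.arg(algorithm)
  comm <- withr::with_seed(seed, {
    if (algorithm == "louvain") {
      igraph::cluster_louvain(g, resolution = resolution)
    } else {
      igraph::cluster_leiden(g, objective_function = "modularity",
                             resolution = resolution, n_iterations = 5)
    }
  })
  mem <- igraph::membership(comm)
  # relabel by decreasing size for stable, readable ids
  sizes <- sort(table(mem), decreasing = TRUE)
  relab <- setNames(as.character(seq_along(sizes) - 1L), names(sizes))
  lab <- unname(relab[as.character(mem)])
  tibble(barcode = igraph::V(g)$name,
         cluster = factor(lab, levels = as.character(seq_along(sizes) - 1L)))
}

#' Rank cluster markers by Welch t-statistic
#'
#' For every cluster, each gene's Welch two-sample t-statistic (cluster vs all
#' other cells) is computed on the log layer; the top `top_n` upregulated
#' genes (positive t only) are returned per cluster, ordered by decreasing t.
#'
#' @param m A [cell_matrix()] with a log layer.
#' @param clusters Tibble from [cluster_graph()] or a vector of labels in cell
#'   order.
#' @param top_n Markers kept per cluster (default 100).
#' @return A `marker_table` tibble: `cluster`, `rank`, `gene`, `t`, `p_value`.
#'   Clusters with fewer than 3 cells are skipped with a warning.
#' @export
rank_markers_ttest <- function(m, clusters, top_n = 100) {
  x <- .log_layer(m)
  lab <- .cluster_vector(clusters, m)
  out <- list()
  for (cl in levels(factor(lab))) {
    idx <- which(lab == cl)
    if (length(idx) < 3L || n_cells(m) - length(idx) < 3L) {
      warn(sprintf("cluster %s has too few cells for marker ranking; skipped", cl))
      next
    }
    ts <- .welch_t_cols(x, idx)
    keep <- which(ts$t > 0)
    keep <- keep[order(-ts$t[keep])][seq_len(min(top_n, length(keep)))]
    if (!length(keep)) next
    out[[cl]] <- tibble(cluster = cl, rank = seq_along(keep),
                        gene = colnames(x)[keep],
                        t = ts$t[keep], p_value = ts$p[keep])
  }
  res <- dplyr::bind_rows(out)
  class(res) <- c("marker_table", class(res))
  res
}

# vectorized Welch t per column: group idx vs the rest
.welch_t_cols <- function(x, idx) {
  a <- x[idx, , drop = FALSE]
  b <- x[-idx, , drop = FALSE]
  na <- nrow(a); nb <- nrow(b)
  ma <- Matrix::colSums(a) / na
  mb <- Matrix::colSums(b) / nb
  va <- (Matrix::colSums(a^2) / na - ma^2) * na / (na - 1)
  vb <- (Matrix::colSums(b^2) / nb - mb^2) * nb / (nb - 1)
  se2 <- va / na + vb / nb
  t <- ifelse(se2 > 0, (ma - mb) / sqrt(se2), 0)
  df <- ifelse(se2 > 0,
               se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1)),
               1)
  p <- 2 * pt(abs(t), df = df, lower.tail = FALSE)
  list(t = as.numeric(t), p = as.numeric(p))
}

.cluster_vector <- function(clusters, m) {
  if (is.data.frame(clusters)) {
    i <- match(m$obs$barcode, clusters$barcode)
    if (anyNA(i)) abort("cluster table does not cover all cells")
    as.character(clusters$cluster)[i]
  } else {
    if (length(clusters) != n_cells(m)) abort("cluster labels must match cell count")
    as.character(clusters)
  }
}

#' Annotate clusters by marker overlap with a reference
#'
#' Scores every cluster against every reference marker set with the overlap
#' coefficient |top markers ∩ reference| / min(#top markers, #reference); the
#' best label wins, ties broken by larger raw intersection then lexical label
#' order. Clusters overlapping nothing are labelled `"unassigned"`.
#'
#' @param markers A `marker_table` from [rank_markers_ttest()].
#' @param reference Named list of MARKER [gene_set()]s (e.g.
#'   [retinal_marker_sets()]).
#' @return A `cluster_labeling` tibble: `cluster`, `label`, `overlap_score`,
#'   `runner_up`, `runner_up_score`.
#' @export
annotate_clusters_overlap <- function(markers, reference) {
  if (!length(reference)) abort("reference marker sets must be non-empty")
  ref_syms <- lapply(reference, set_symbols)
  labels <- names(reference) %||% vapply(reference, `[[`, "", "name")
  names(ref_syms) <- labels
  out <- lapply(split(markers$gene, markers$cluster), function(top) {
    inter <- vapply(ref_syms, function(r) length(intersect(top, r)), 0L)
    denom <- vapply(ref_syms, function(r) min(length(top), length(r)), 0L)
    score <- ifelse(denom > 0, inter / denom, 0)
    ord <- order(-score, -inter, labels)
    best <- ord[1]
    second <- if (length(ord) > 1) ord[2] else NA_integer_
    tibble(
      label = if (score[best] == 0) "unassigned" else labels[best],
      overlap_score = unname(score[best]),
      runner_up = if (is.na(second)) NA_character_ else labels[second],
      runner_up_score = if (is.na(second)) NA_real_ else unname(score[second])
    )
  })
  res <- dplyr::bind_rows(out, .id = "cluster")
  class(res) <- c("cluster_labeling", class(res))
  res
}
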