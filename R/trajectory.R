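#' Subset a lineage by cluster label
#'
#' Row-subsets a cell matrix to the cells whose cluster (or cell-type label)
#' is in `keep`, preserving all layers and metadata.
#'
#' @param m A [cell_matrix()].
#' @param keep Character vector of labels to retain.
#' @param column Metadata column holding the labels (default `"cluster"`).
#' @return The subset [cell_matrix()].
#' @export
subset_lineage <- function(m, keep, column = "cluster") {
  if (!column %in% names(m$obs)) abort(sprintf("no '%s' column in cell metadata", column))
  lab <- as.character(m$obs[[column]])
  missing <- setdiff(keep, unique(lab))
  if (length(missing)) abort(sprintf("labels not present: %s", paste(missing, collapse = ", ")))
  idx <- lab %in% keep
  if (!any(idx)) abort("lineage subset is empty")
  subset_cells(m, idx)
}

#' Select a pseudotime root cell
#'
#' Returns the cell maximizing a criterion score (by default a G2/M
#' cell-cycle score, so the root sits among actively cycling progenitors).
#' Ties break deterministically to the lexicographically first barcode.
#'
#' @param m A [cell_matrix()].
#' @param criterion Metadata column holding the criterion score.
#' @param within Optional cluster label restricting the candidate cells.
#' @param column Metadata column holding cluster labels (used with `within`).
#' @return The root cell barcode (length-1 character).
#' @export
select_root <- function(m, criterion = "score_G2M", within = NULL,
                        column = "cluster") {
  if (!criterion %in% names(m$obs)) {
    abort(sprintf("criterion column '%s' not found; compute it first", criterion))
  }
  o <- m$obs
  if (!is.null(within)) o <- o[as.character(o[[column]]) %in% within, , drop = FALSE]
  if (!nrow(o)) abort("no candidate cells for root selection")
  v <- o[[criterion]]
  cand <- o$barcode[v == max(v, na.rm = TRUE)]
  sort(cand)[1]
}

#' Diffusion pseudotime from an embedding
#'
#' Builds a kNN Gaussian kernel with locally adaptive bandwidth (per-cell
#' bandwidth = distance to the ceiling(k/2)-th neighbor), density-normalizes
#' it, forms the Markov transition matrix, and takes its top `n_comps`
#' nontrivial right eigenvectors psi_i with eigenvalues lambda_i. The
#' pseudotime of a cell is its Euclidean distance from the root in the space
#' of components scaled by lambda_i / (1 - lambda_i). Cells disconnected from
#' the root's kernel component get infinite pseudotime and are flagged.
#'
#' @param coords A [embed_pca()] result or cells x dims matrix with barcode
#'   rownames.
#' @param root Root cell barcode (pseudotime 0).
#' @param k Neighbor count of the kernel (default 15).
#' @param n_comps Number of nontrivial diffusion components (default 10).
#' @return A `pseudotime_result` tibble: `barcode`, `pseudotime`, `finite`;
#'   attributes `root`, `eigenvalues`, `eigenvectors` (including the trivial
#'   first), `n_comps`.
#' @export
diffusion_pseudotime <- function(coords, root, k = 15, n_comps = 10) {
  x <- .pca_coords(coords)
  n <- nrow(x)
  if (is.null(rownames(x))) rownames(x) <- as.character(seq_len(n))
  if (!root %in% rownames(x)) abort("root cell not found in coordinates")
  if (n_comps < 2) abort("n_comps must be >= 2")
  kern <- .adaptive_kernel(as.matrix(dist(x)), k)
  eig <- .transition_eigen(kern, n_comps)
  comp <- .kernel_components(kern)
  root_i <- match(root, rownames(x))
  in_comp <- comp == comp[root_i]
  lam <- eig$values[-1]
  psi <- eig$vectors[, -1, drop = FALSE]
  scale <- lam / (1 - lam)
  diff_coords <- sweep(psi, 2, scale, `*`)
  delta <- sweep(diff_coords, 2, diff_coords[root_i, ], `-`)
  pt <- sqrt(rowSums(delta^2))
  pt[!in_comp] <- Inf
  if (any(!in_comp)) {
    warn(sprintf("%d cells disconnected from the root component; pseudotime = Inf",
                 sum(!in_comp)))
  }
  out <- tibble(barcode = rownames(x), pseudotime = pt, finite = in_comp)
  attr(out, "root") <- root
  attr(out, "eigenvalues") <- eig$values
  attr(out, "eigenvectors") <- eig$vectors
  attr(out, "n_comps") <- n_comps
  class(out) <- c("pseudotime_result", class(out))
  out
}

# kNN-truncated Gaussian kernel, adaptive bandwidth sigma_i = distance to the
# ceil(k/2)-th neighbor; symmetrized by union; self-affinity 1
.adaptive_kernel <- function(d, k) {
  n <- nrow(d)
  if (k >= n) abort("k must be smaller than the number of cells")
  nb <- .knn_indices(d, k)
  sigma <- vapply(seq_len(n), function(i) d[i, nb[i, ceiling(k / 2)]], 0)
  sigma[sigma == 0] <- min(sigma[sigma > 0], 1e-12)
  kmat <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- nb[i, ]
    kmat[i, j] <- exp(-d[i, j]^2 / (sigma[i] * sigma[j]))
  }
  kmat <- pmax(kmat, t(kmat))
  diag(kmat) <- 1
  kmat
}

# density-normalized transition operator; right eigenvectors via the
# symmetric conjugate S = D^-1/2 W D^-1/2
.transition_eigen <- function(kmat, n_comps) {
  q <- rowSums(kmat)
  w <- kmat / outer(q, q)
  dw <- rowSums(w)
  s <- w / outer(sqrt(dw), sqrt(dw))
  s <- (s + t(s)) / 2
  e <- eigen(s, symmetric = TRUE)
  m <- n_comps + 1L
  vals <- pmin(e$values[seq_len(m)], 1 - 1e-12)
  vecs <- e$vectors[, seq_len(m), drop = FALSE] / sqrt(dw)
  # stabilize eigenvector sign: largest-magnitude entry positive
  for (j in seq_len(ncol(vecs))) {
    i <- which.max(abs(vecs[, j]))
    if (vecs[i, j] < 0) vecs[, j] <- -vecs[, j]
  }
  list(values = vals, vectors = vecs)
}

.kernel_components <- function(kmat) {
  g <- igraph::graph_from_adjacency_matrix(kmat > 0, mode = "undirected",
                                           diag = FALSE)
  igraph::components(g)$membership
}

#' Bin pathway scores along pseudotime
#'
#' Equal-count (quantile) bins on the pseudotime rank; per bin and pathway the
#' mean score and a normal-approximation 95% CI (1.96 * sd / sqrt(n)) are
#' reported. Excluded (zero-score) cells and cells with non-finite pseudotime
#' must not contribute and are dropped here defensively.
#'
#' @param scores A `pathway_scores` tibble ([score_dsb()] output).
#' @param pt A `pseudotime_result` ([diffusion_pseudotime()] output).
#' @param n_bins Number of bins (default 20, minimum 2).
#' @return A `trajectory_curve` tibble: `pathway`, `bin`, `midpoint`, `n`,
#'   `mean`, `ci_lo`, `ci_hi` (CI is `NA` for singleton bins).
#' @export
bin_curve <- function(scores, pt, n_bins = 20) {
  if (n_bins < 2) abort("n_bins must be >= 2")
  d <- dplyr::inner_join(
    dplyr::filter(scores, !.data$excluded),
    dplyr::filter(pt, .data$finite),
    by = "barcode"
  )
  if (!nrow(d)) abort("no usable cells after exclusion")
  out <- d |>
    dplyr::group_by(.data$set_name) |>
    dplyr::mutate(bin = dplyr::ntile(.data$pseudotime, n_bins)) |>
    dplyr::group_by(.data$set_name, .data$pathway, .data$bin) |>
    dplyr::summarise(
      midpoint = mean(.data$pseudotime),
      n = dplyr::n(),
      mean = mean(.data$score),
      sd = sd(.data$score),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      ci_half = ifelse(.data$n >= 2, 1.96 * .data$sd / sqrt(.data$n), NA_real_),
      ci_lo = .data$mean - .data$ci_half,
      ci_hi = .data$mean + .data$ci_half
    ) |>
    dplyr::select("set_name", "pathway", "bin", "midpoint", "n",
                  "mean", "ci_lo", "ci_hi") |>
    dplyr::arrange(.data$set_name, .data$bin)
  class(out) <- c("trajectory_curve", class(out))
  out
}

#' Polynomial fit to a binned trajectory curve
#'
#' Least-squares polynomial of the given degree on (bin midpoint, bin mean),
#' one fit per gene set.
#'
#' @param curve A `trajectory_curve` from [bin_curve()].
#' @param degree Polynomial degree (default 3); needs at least `degree + 1`
#'   bins with defined means.
#' @return A `trajectory_fit` tibble: `set_name`, `degree`, `term` (power of
#'   pseudotime, 0-based), `coefficient`; attribute `residuals` summarises the
#'   per-set residual standard deviation.
#' @export
polyfit_curve <- function(curve, degree = 3) {
  fits <- lapply(split(curve, curve$set_name), function(cu) {
    cu <- cu[is.finite(cu$mean), , drop = FALSE]
    if (nrow(cu) < degree + 1) {
      abort(sprintf("set %s: %d bins cannot support degree %d",
                    cu$set_name[1], nrow(cu), degree))
    }
    X <- outer(cu$midpoint, 0:degree, `^`)
    beta <- qr.coef(qr(X), cu$mean)
    r <- cu$mean - as.numeric(X %*% beta)
    list(coef = unname(beta), rsd = unname(sd(r)))
  })
  out <- dplyr::bind_rows(lapply(names(fits), function(nm) {
    tibble(set_name = nm, degree = degree,
           term = 0:degree, coefficient = fits[[nm]]$coef)
  }))
  attr(out, "residuals") <- tibble(
    set_name = names(fits),
    residual_sd = unname(vapply(fits, `[[`, 0, "rsd"))
  )
  class(out) <- c("trajectory_fit", class(out))
  out
}

#' Evaluate a trajectory polynomial fit
#'
#' @param fit A `trajectory_fit` from [polyfit_curve()].
#' @param at Pseudotime values at which to evaluate.
#' @return Tibble: `set_name`, `pseudotime`, `fitted`.
#' @export
predict_curve <- function(fit, at) {
  dplyr::bind_rows(lapply(split(fit, fit$set_name), function(f) {
    tibble(set_name = f$set_name[1], pseudotime = at,
           fitted = as.numeric(outer(at, f$term, `^`) %*% f$coefficient))
  }))
}
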