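#' Score a gene set per cell
#'
#' The pathway score of a cell is the arithmetic mean of its raw UMI counts
#' over the set members present in the gene panel (absent members are dropped
#' from the denominator, so panel coverage is not conflated with activity).
#' Cells whose score is exactly 0 — typically dropout-driven — are flagged
#' `excluded` and must be left out of downstream comparisons.
#'
#' @param m A [cell_matrix()].
#' @param set A [gene_set()].
#' @param use `"counts"` (raw UMIs, the defining choice) or `"lognorm"`
#'   (sensitivity analysis only).
#' @return A `pathway_scores` tibble: `barcode`, `set_name`, `pathway`,
#'   `score`, `excluded`; attributes `genes_present` (symbols found) and
#'   `genes_missing`.
#' @export
#' @examples
#' m <- cell_matrix(matrix(1L, 2, 4, dimnames = list(
#'   c("a", "b"), c("XRCC5", "XRCC6", "TP53BP1", "WRN"))))
#' score_gene_set(m, load_dsb_sets("human")$NHEJ)
score_gene_set <- function(m, set, use = c("counts", "lognorm")) {
  use <- match.arg(use)
  stopifnot(inherits(m, "cell_matrix"), inherits(set, "gene_set"))
  x <- if (use == "counts") m$counts else .log_layer(m)
  present <- intersect(set_symbols(set), colnames(x))
  missing <- setdiff(set_symbols(set), colnames(x))
  if (!length(present)) {
    abort(sprintf("no member of gene set '%s' found in the panel", set$name),
          class = "dsbscore_missing_gene_set")
  }
  if (length(missing)) {
    inform(sprintf("score_gene_set(%s): %d/%d genes absent from panel (%s)",
                   set$name, length(missing), length(set_symbols(set)),
                   paste(missing, collapse = ", ")))
  }
  score <- as.numeric(Matrix::rowSums(x[, present, drop = FALSE])) / length(present)
  out <- tibble(barcode = m$obs$barcode, set_name = set$name,
                pathway = set$pathway, score = score, excluded = score == 0)
  attr(out, "genes_present") <- present
  attr(out, "genes_missing") <- missing
  class(out) <- c("pathway_scores", class(out))
  out
}

#' Score the three DSB repair pathways per cell
#'
#' Applies [score_gene_set()] to the curated NHEJ, MMEJ and HDR sets rendered
#' in the species' nomenclature, returning one long tibble.
#'
#' @param m A [cell_matrix()].
#' @param species Species whose symbol convention matches the matrix.
#' @param use Count layer, as in [score_gene_set()].
#' @return A `pathway_scores` tibble with one row per cell and pathway.
#' @export
score_dsb <- function(m, species = "human", use = c("counts", "lognorm")) {
  use <- match.arg(use)
  sets <- load_dsb_sets(species)
  out <- dplyr::bind_rows(lapply(sets, function(s) score_gene_set(m, s, use = use)))
  class(out) <- c("pathway_scores", class(out))
  out
}

#' Score cell-cycle phase gene sets per cell
#'
#' Same averaging rule as [score_gene_set()], one score per phase set.
#'
#' @param m A [cell_matrix()].
#' @param sets Named list of CELL_CYCLE [gene_set()]s (default: packaged
#'   stand-in G2M and S sets for the given species).
#' @param species Used only to pick the default sets.
#' @param use Count layer, as in [score_gene_set()].
#' @return A `pathway_scores` tibble (`set_name` holds the phase).
#' @export
score_cell_cycle <- function(m, sets = NULL, species = "human",
                             use = c("counts", "lognorm")) {
  use <- match.arg(use)
  sets <- sets %||% cell_cycle_sets(species)
  out <- dplyr::bind_rows(lapply(sets, function(s) score_gene_set(m, s, use = use)))
  class(out) <- c("pathway_scores", class(out))
  out
}

#' Pivot pathway scores to one column per set
#'
#' @param scores A `pathway_scores` tibble.
#' @param drop_excluded Drop rows flagged excluded before pivoting.
#' @return Wide tibble: `barcode` plus one score column per set.
#' @export
scores_wide <- function(scores, drop_excluded = FALSE) {
  s <- scores
  if (drop_excluded) s <- dplyr::filter(s, !.data$excluded)
  tidyr::pivot_wider(s[c("barcode", "set_name", "score")],
                     names_from = "set_name", values_from = "score")
}

# ---- group comparison -------------------------------------------------------

#' Compare score distributions between two groups
#'
#' Implements the normality-gated testing rule: each group is checked with a
#' Shapiro-Wilk test at `alpha_gate`; if both pass, a t-test is used (Welch
#' by default, Student paired if `paired`), otherwise a rank-based fallback
#' (Wilcoxon signed-rank if paired, rank-sum otherwise). Zero-score exclusion
#' must have been applied upstream — pass only non-excluded scores.
#'
#' @param data Data frame with one score column and one group column, or a
#'   named list of two numeric vectors.
#' @param score,group Column names when `data` is a data frame.
#' @param paired Treat observations as paired (requires equal group sizes in
#'   matching order).
#' @param alpha_gate Significance level of the normality gate (default 0.05).
#' @return A `dsb_comparison` object; see [tidy.dsb_comparison()] and
#'   [glance.dsb_comparison()].
#' @export
compare_scores <- function(data, score = "score", group = "group",
                           paired = FALSE, alpha_gate = 0.05) {
  if (is.data.frame(data)) {
    vecs <- split(data[[score]], data[[group]])
  } else {
    vecs <- data
  }
  if (length(vecs) != 2L) abort("compare_scores needs exactly two groups")
  labels <- names(vecs) %||% c("group1", "group2")
  if (any(lengths(vecs) < 3L)) {
    abort("each group needs at least 3 observations",
          class = "dsbscore_insufficient_sample")
  }
  gate_p <- vapply(vecs, .shapiro_p, 0)
  gate_pass <- all(gate_p > alpha_gate)
  x <- vecs[[1]]; y <- vecs[[2]]
  if (gate_pass) {
    ht <- t.test(x, y, paired = paired, var.equal = FALSE)
    test <- if (paired) "paired t-test" else "Welch t-test"
  } else if (paired) {
    ht <- suppressWarnings(wilcox.test(x, y, paired = TRUE, exact = FALSE))
    test <- "Wilcoxon signed-rank"
  } else {
    ht <- suppressWarnings(wilcox.test(x, y, exact = FALSE))
    test <- "Wilcoxon rank-sum"
  }
  structure(list(
    groups = labels, n = lengths(vecs), means = vapply(vecs, mean, 0),
    test = test, statistic = unname(ht$statistic), p_value = ht$p.value,
    gate = tibble(group = labels, shapiro_p = unname(gate_p),
                  normal = unname(gate_p > alpha_gate)),
    alpha_gate = alpha_gate, paired = paired
  ), class = "dsb_comparison")
}

# Shapiro-Wilk is defined for 3..5000 observations; larger groups are
# assessed on a deterministic evenly-spaced subsample of 5000
.shapiro_p <- function(v) {
  if (length(v) > 5000) v <- v[round(seq(1, length(v), length.out = 5000))]
  if (length(unique(v)) == 1L) return(0)  # degenerate: not normal
  shapiro.test(v)$p.value
}

#' @export
print.dsb_comparison <- function(x, ...) {
  cat(sprintf("<dsb_comparison> %s vs %s: %s, statistic = %.4g, p = %.4g\n",
              x$groups[1], x$groups[2], x$test, x$statistic, x$p_value))
  cat(sprintf("  means: %.4g vs %.4g; gate (Shapiro p): %.3g / %.3g\n",
              x$means[1], x$means[2], x$gate$shapiro_p[1], x$gate$shapiro_p[2]))
  invisible(x)
}

#' Tidy a group comparison
#'
#' @param x A `dsb_comparison`.
#' @param ... Unused.
#' @return One-row tibble with groups, means, test, statistic, p-value and
#'   the per-group normality-gate p-values.
#' @export
tidy.dsb_comparison <- function(x, ...) {
  tibble(group1 = x$groups[1], group2 = x$groups[2],
         n1 = x$n[1], n2 = x$n[2],
         mean1 = x$means[1], mean2 = x$means[2],
         test = x$test, statistic = x$statistic, p_value = x$p_value,
         shapiro_p1 = x$gate$shapiro_p[1], shapiro_p2 = x$gate$shapiro_p[2])
}

#' @rdname tidy.dsb_comparison
#' @export
glance.dsb_comparison <- function(x, ...) {
  tibble(test = x$test, statistic = x$statistic, p_value = x$p_value,
         gate_passed = all(x$gate$normal))
}
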