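#' Bulk expression container
#'
#' Genes x samples expression values (TPM or normalized counts) plus a
#' per-sample metadata tibble.
#'
#' @param values Non-negative genes x samples matrix with gene rownames and
#'   sample colnames.
#' @param samples Data frame with a `sample` column matching `colnames(values)`
#'   plus any of `species`, `condition`, `day`, `replicate`.
#' @return A `bulk_table` object.
#' @export
bulk_table <- function(values, samples = NULL) {
  values <- as.matrix(values)
  if (any(values < 0)) abort("bulk expression values must be non-negative")
  if (is.null(colnames(values))) colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
  if (is.null(rownames(values))) abort("values must have gene rownames")
  if (is.null(samples)) samples <- tibble(sample = colnames(values))
  samples <- as_tibble(samples)
  if (!"sample" %in% names(samples)) abort("samples needs a 'sample' column")
  if (!identical(samples$sample, colnames(values))) {
    abort("samples$sample must match colnames(values) in order")
  }
  structure(list(values = values, samples = samples), class = "bulk_table")
}

#' @export
print.bulk_table <- function(x, ...) {
  cat(sprintf("<bulk_table> %d genes x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(unique(x$samples$species %||% "unannotated"), collapse = ", ")))
  invisible(x)
}

#' @export
dim.bulk_table <- function(x) dim(x$values)

#' @export
tidy.bulk_table <- function(x, ...) {
  dplyr::left_join(
    tidyr::pivot_longer(
      dplyr::bind_cols(tibble(gene = rownames(x$values)),
                       as_tibble(x$values, .name_repair = "minimal")),
      -"gene", names_to = "sample", values_to = "value"),
    x$samples, by = "sample")
}

#' Read a bulk table from TSV
#'
#' @param path Genes x samples TSV (first column gene symbol, header row of
#'   sample names).
#' @param samples_path Optional sample-metadata TSV with columns `sample`,
#'   `species`, `condition`, `day`, `replicate` (any subset beyond `sample`).
#' @return A [bulk_table()].
#' @export
read_bulk_tsv <- function(path, samples_path = NULL) {
  d <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  values <- as.matrix(d[, -1, drop = FALSE])
  rownames(values) <- d[[1]]
  samples <- if (!is.null(samples_path)) {
    as_tibble(read.delim(samples_path, stringsAsFactors = FALSE))
  } else NULL
  if (!is.null(samples)) samples <- samples[match(colnames(values), samples$sample), ]
  bulk_table(values, samples)
}

#' Write a bulk table to TSV
#'
#' @param t A [bulk_table()].
#' @param path Output TSV path; sample metadata goes to `<path>.samples.tsv`.
#' @return `path`, invisibly.
#' @export
write_bulk_tsv <- function(t, path) {
  write.table(data.frame(gene = rownames(t$values), t$values, check.names = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(t$samples, paste0(path, ".samples.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' log2(x + 1) transform of a bulk table
#'
#' The bulk analyses work on log-transformed TPM; base 2 with a unit
#' pseudocount is fixed for the bulk module (the single-cell module uses
#' natural log1p).
#'
#' @param t A [bulk_table()].
#' @return The transformed [bulk_table()]; metadata unchanged.
#' @export
log_tpm <- function(t) {
  stopifnot(inherits(t, "bulk_table"))
  if (any(t$values < 0)) abort("negative values cannot be log-transformed")
  t$values <- log2(t$values + 1)
  t
}

#' Quantile normalization within sample groups
#'
#' Classic quantile normalization applied independently within each group
#' (e.g. species): every sample's rank-r value is replaced by the mean of the
#' rank-r values across the group's samples; tied entries receive the mean of
#' their tied target values, so the defining property (identical sorted
#' vectors within a group) holds exactly. Groups of size 1 pass through with
#' a warning.
#'
#' @param t A [bulk_table()].
#' @param grouping Sample-metadata column defining the groups (default
#'   `"species"`; `NULL` normalizes all samples together).
#' @return The normalized [bulk_table()].
#' @export
quantile_normalize <- function(t, grouping = "species") {
  stopifnot(inherits(t, "bulk_table"))
  groups <- if (is.null(grouping)) rep("all", ncol(t$values))
            else as.character(t$samples[[grouping]])
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) < 2L) {
      warn(sprintf("quantile_normalize: group '%s' has a single sample; passed through", g))
      next
    }
    t$values[, idx] <- .quantile_normalize_matrix(t$values[, idx, drop = FALSE])
  }
  t
}

# columns = samples; target distribution = row means of the sorted columns;
# a tie group takes the mean of all target values at the ranks it occupies
.quantile_normalize_matrix <- function(x) {
  target <- rowMeans(apply(x, 2, sort))
  out <- x
  for (j in seq_len(ncol(x))) {
    v <- x[, j]
    pos <- rank(v, ties.method = "first")  # occupied sorted positions
    out[, j] <- ave(target[pos], v, FUN = mean)
  }
  out
}

#' Annotate a bulk table with the curated DSB pathway sets
#'
#' Builds the long pathway table: one row per sample and DSB gene present in
#' the table, annotated with its pathway. Genes absent from a species' table
#' are reported; a pathway with no genes present for some species is an
#' error.
#'
#' @param t A [bulk_table()] (typically quantile-normalized and
#'   log-transformed).
#' @param species Species whose symbol convention matches the rownames;
#'   default: per-sample `species` metadata (must then be single-species per
#'   call or use [pathway_long_bind()] over tables).
#' @return A `pathway_long` tibble: `species`, `sample`, `pathway`, `gene`,
#'   `expr` plus any sample metadata columns.
#' @export
build_pathway_table <- function(t, species = NULL) {
  stopifnot(inherits(t, "bulk_table"))
  species <- species %||% unique(as.character(t$samples$species))
  if (length(species) != 1L) abort("bulk table must be single-species; got multiple")
  sets <- load_dsb_sets(species)
  sets_hu <- load_dsb_sets("human")
  rows <- list()
  for (nm in names(sets)) {
    s <- sets[[nm]]
    # species nomenclature first; ortholog-mapped tables conventionally carry
    # human-style symbols, so fall back per gene to the human reference symbol
    sym_sp <- set_symbols(s)
    sym_hu <- set_symbols(sets_hu[[nm]])
    rn <- rownames(t$values)
    resolved <- ifelse(sym_sp %in% rn, sym_sp,
                       ifelse(sym_hu %in% rn, sym_hu, NA_character_))
    present <- resolved[!is.na(resolved)]
    missing <- sym_sp[is.na(resolved)]
    if (!length(present)) {
      abort(sprintf("species %s: no %s gene present in the table", species, s$name),
            class = "dsbscore_missing_gene_set")
    }
    if (length(missing)) {
      inform(sprintf("build_pathway_table(%s/%s): absent genes %s",
                     species, s$name, paste(missing, collapse = ", ")))
    }
    sub <- t$values[present, , drop = FALSE]
    rows[[s$name]] <- tibble(
      species = species,
      sample = rep(colnames(sub), each = nrow(sub)),
      pathway = s$pathway,
      gene = rep(rownames(sub), times = ncol(sub)),
      expr = as.vector(sub)
    )
  }
  out <- dplyr::left_join(dplyr::bind_rows(rows),
                          dplyr::select(t$samples, -dplyr::any_of("species")),
                          by = "sample")
  class(out) <- c("pathway_long", class(out))
  out
}

#' Bind per-species pathway tables
#'
#' @param tables List of [bulk_table()]s (one per species).
#' @return Combined `pathway_long` tibble.
#' @export
pathway_long_bind <- function(tables) {
  out <- dplyr::bind_rows(lapply(tables, build_pathway_table))
  class(out) <- c("pathway_long", class(out))
  out
}

# ---- Wilcoxon signed-rank ---------------------------------------------------

#' Exact Wilcoxon signed-rank test
#'
#' Paired signed-rank test with the null distribution obtained by full
#' enumeration of all 2^n sign assignments when the number of nonzero
#' differences is at most `exact_max_n` (default 12), and by a tie-corrected
#' normal approximation with continuity correction above. Zero differences
#' are dropped (Wilcoxon's convention); ties in |difference| receive average
#' ranks. The two-sided p-value is `2 * min(P(W <= w), P(W >= w))`, capped at
#' 1; with no nonzero differences the statistic sits at its null center and
#' p = 1.
#'
#' @param x Numeric vector (differences, or first member of each pair).
#' @param y Optional second member of each pair (`x - y` is tested).
#' @param exact_max_n Largest n for exact enumeration.
#' @return List: `statistic` (W+, the positive-rank sum), `p_value`, `n_used`
#'   (nonzero pairs), `method` (`"exact"` or `"normal"`).
#' @export
#' @examples
#' wilcoxon_signed_rank(c(-1, -2, -3))$p_value  # 0.25 = 2/8
wilcoxon_signed_rank <- function(x, y = NULL, exact_max_n = 12) {
  d <- if (is.null(y)) x else x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(list(statistic = 0, p_value = 1, n_used = 0L, method = "degenerate"))
  }
  r <- rank(abs(d), ties.method = "average")
  w <- sum(r[d > 0])
  if (n <= exact_max_n) {
    # all 2^n sign assignments; with average ranks the support may be
    # non-integer, so enumerate W+ values directly
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    wdist <- as.vector(signs %*% r)
    p_le <- mean(wdist <= w + 1e-9)
    p_ge <- mean(wdist >= w - 1e-9)
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal"
  }
  list(statistic = w, p_value = p, n_used = n, method = method)
}

#' Pairwise pathway contrasts within species
#'
#' For each species and each pathway pair, the per-replicate pathway mean
#' expression is computed (mean over the pathway's genes within each sample)
#' and the replicate-paired means are compared with the exact Wilcoxon
#' signed-rank test ([wilcoxon_signed_rank()]). Pathways have unequal gene
#' counts, so the replicate-level mean is the pairing unit.
#'
#' @param p A `pathway_long` tibble ([build_pathway_table()] /
#'   [pathway_long_bind()]).
#' @param species Optional subset of species to test.
#' @return Tibble: `species`, `pathway_a`, `pathway_b`, `n_pairs`, `mean_a`,
#'   `mean_b`, `statistic`, `p_value`, `method`, `direction` (sign of
#'   mean_a - mean_b).
#' @export
pairwise_pathway_tests <- function(p, species = NULL) {
  d <- if (is.null(species)) p else dplyr::filter(p, .data$species %in% !!species)
  means <- d |>
    dplyr::group_by(.data$species, .data$sample, .data$pathway) |>
    dplyr::summarise(mean_expr = mean(.data$expr), .groups = "drop")
  out <- list()
  for (sp in unique(means$species)) {
    msp <- dplyr::filter(means, .data$species == sp)
    wide <- tidyr::pivot_wider(msp, names_from = "pathway", values_from = "mean_expr")
    pws <- intersect(c("NHEJ", "MMEJ", "HDR"), names(wide))
    if (nrow(wide) < 2L) abort(sprintf("species %s: need >= 2 replicates", sp))
    for (i in seq_along(pws)) for (j in seq_along(pws)) {
      if (i >= j) next
      a <- wide[[pws[i]]]; b <- wide[[pws[j]]]
      wt <- wilcoxon_signed_rank(a, b)
      out[[length(out) + 1L]] <- tibble(
        species = sp, pathway_a = pws[i], pathway_b = pws[j],
        n_pairs = wt$n_used, mean_a = mean(a), mean_b = mean(b),
        statistic = wt$statistic, p_value = wt$p_value, method = wt$method,
        direction = sign(mean(a) - mean(b))
      )
    }
  }
  dplyr::bind_rows(out)
}

#' Time-course gene-set summary
#'
#' Per time point and gene set: mean of the (transformed) expression over all
#' set genes and replicates at that time, with a normal 95% CI. Time points
#' with a single replicate are flagged (`ci_over` = "genes").
#'
#' @param t A [bulk_table()] with `day` sample metadata.
#' @param sets Named list of [gene_set()]s (e.g. DSB sets plus G2M).
#' @return Tibble: `set_name`, `day`, `n_values`, `n_replicates`, `mean`,
#'   `ci_lo`, `ci_hi`, `ci_over`.
#' @export
timecourse_summary <- function(t, sets) {
  stopifnot(inherits(t, "bulk_table"))
  if (!"day" %in% names(t$samples)) abort("sample metadata needs a 'day' column")
  out <- list()
  for (s in sets) {
    present <- intersect(set_symbols(s), rownames(t$values))
    if (!length(present)) next
    for (d in sort(unique(t$samples$day))) {
      cols <- which(t$samples$day == d)
      v <- as.vector(t$values[present, cols, drop = FALSE])
      ci <- 1.96 * sd(v) / sqrt(length(v))
      out[[length(out) + 1L]] <- tibble(
        set_name = s$name, day = d,
        n_values = length(v), n_replicates = length(cols),
        mean = mean(v), ci_lo = mean(v) - ci, ci_hi = mean(v) + ci,
        ci_over = if (length(cols) > 1) "genes x replicates" else "genes"
      )
    }
  }
  dplyr::bind_rows(out)
}

#' DSB-gene PCA and Spearman correlation across samples
#'
#' Merges samples from several bulk tables on their shared DSB genes, then
#' runs PCA over samples (features = DSB genes, centered) and computes the
#' full pairwise Spearman rank correlation (average ranks for ties).
#' Zero-variance genes are dropped with a note.
#'
#' @param tables List of [bulk_table()]s (log scale recommended); symbols must
#'   be comparable (human-style upper case).
#' @param species Species whose curated sets define the DSB gene universe
#'   (default `"human"`).
#' @return A `dsb_pca_spearman` object: `coords` (sample scores tibble),
#'   `var_explained`, `spearman` (sample x sample matrix), `genes` used.
#' @export
dsb_pca_spearman <- function(tables, species = "human") {
  if (inherits(tables, "bulk_table")) tables <- list(tables)
  sets <- load_dsb_sets(species)
  universe <- unlist(lapply(sets, set_symbols), use.names = FALSE)
  shared <- Reduce(intersect, lapply(tables, function(t) rownames(t$values)))
  genes <- intersect(universe, shared)
  if (length(genes) < 3L) abort("fewer than 3 shared DSB genes across tables")
  mat <- do.call(cbind, lapply(tables, function(t) t$values[genes, , drop = FALSE]))
  colnames(mat) <- make.unique(unlist(lapply(tables, function(t) colnames(t$values))))
  keep <- if (ncol(mat) < 2) rep(TRUE, nrow(mat)) else apply(mat, 1, var) > 0
  if (any(!keep)) {
    inform(sprintf("dsb_pca_spearman: dropping %d zero-variance genes", sum(!keep)))
    mat <- mat[keep, , drop = FALSE]
    genes <- genes[keep]
  }
  samples <- dplyr::bind_rows(lapply(tables, function(t) t$samples))
  samples$sample <- colnames(mat)
  p <- prcomp(Matrix::t(mat), center = TRUE, scale. = FALSE)
  n_pc <- min(5L, ncol(p$x))
  coords <- dplyr::bind_cols(samples,
                             as_tibble(p$x[, seq_len(n_pc), drop = FALSE],
                                       .name_repair = "minimal"))
  rho <- cor(mat, method = "spearman")
  structure(list(coords = coords,
                 var_explained = p$sdev^2 / sum(p$sdev^2),
                 spearman = rho, genes = genes),
            class = "dsb_pca_spearman")
}

#' @export
print.dsb_pca_spearman <- function(x, ...) {
  cat(sprintf("<dsb_pca_spearman> %d samples on %d DSB genes; PC1 %.1f%%\n",
              nrow(x$coords), length(x$genes), 100 * x$var_explained[1]))
  invisible(x)
}
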