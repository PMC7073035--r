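#' End-to-end single-cell DSB scoring analysis
#'
#' Chains the full single-cell analysis: QC filtering -> normalization ->
#' common-HVG selection -> PCA -> kNN graph -> modularity clustering ->
#' marker ranking -> marker-overlap annotation -> DSB and cell-cycle scoring
#' -> lineage subset -> diffusion pseudotime -> binned curves and polynomial
#' fits -> pairwise pathway comparisons. When `out_dir` is given, all tables
#' are written as TSV/JSON together with a provenance log of the effective
#' parameters.
#'
#' @param m A [cell_matrix()] of raw UMI counts.
#' @param species Symbol nomenclature of the matrix.
#' @param preset QC preset name ([qc_preset()]) or a [qc_thresholds()].
#' @param lineage Labels of the annotated clusters forming the trajectory
#'   (default: progenitor/neuroblast/cone/rod, intersected with what the
#'   annotation found).
#' @param reference Marker reference for annotation (default
#'   [retinal_marker_sets()]).
#' @param n_hvg,n_pcs,k,n_comps,n_bins,poly_degree,resolution,algorithm
#'   Stage parameters (see the stage functions).
#' @param seed Seed passed to clustering.
#' @param out_dir Optional output directory for the artifact bundle.
#' @return A list bundle: `matrix`, `clusters`, `markers`, `labels`,
#'   `scores`, `pseudotime`, `curve`, `fit`, `comparisons`, `log`.
#' @export
run_sc_score <- function(m, species = "mouse", preset = "e15_mouse",
                         lineage = c("progenitor", "neuroblast", "cone", "rod"),
                         reference = NULL,
                         n_hvg = 1000, n_pcs = 40, k = 15, n_comps = 10,
                         n_bins = 20, poly_degree = 3, resolution = 1,
                         algorithm = "louvain", seed = 0, out_dir = NULL) {
  log <- list(species = species, n_cells_in = n_cells(m),
              preset = if (is.character(preset)) preset else "custom",
              n_hvg = n_hvg, n_pcs = n_pcs, k = k, n_comps = n_comps,
              n_bins = n_bins, poly_degree = poly_degree,
              resolution = resolution, algorithm = algorithm, seed = seed)
  reference <- reference %||% retinal_marker_sets(species)

  m <- compute_qc_metrics(m)
  m <- filter_cells(m, preset)
  log$n_cells_qc <- n_cells(m)
  m <- normalize_log(m)
  hvg <- select_common_hvg(m, n_per_batch = n_hvg)
  log$n_hvg <- length(hvg)
  pca <- embed_pca(m, genes = hvg, n_pcs = n_pcs)
  g <- knn_graph(pca, k = k)
  clusters <- cluster_graph(g, resolution = resolution, seed = seed,
                            algorithm = algorithm)
  m$obs$cluster <- clusters$cluster
  markers <- rank_markers_ttest(m, clusters)
  labels <- annotate_clusters_overlap(markers, reference)
  m$obs$label <- labels$label[match(as.character(m$obs$cluster), labels$cluster)]
  log$n_clusters <- nrow(labels)

  scores <- score_dsb(m, species = species)
  cc <- score_cell_cycle(m, species = species)
  m$obs$score_G2M <- cc$score[cc$set_name == "G2M"]

  lineage_found <- intersect(lineage, unique(m$obs$label))
  if (!length(lineage_found)) {
    warn("no annotated lineage cluster found; using all cells for pseudotime")
    ml <- m
  } else {
    ml <- subset_lineage(m, lineage_found, column = "label")
  }
  log$lineage <- lineage_found
  log$n_cells_lineage <- n_cells(ml)
  root <- select_root(ml, criterion = "score_G2M")
  pca_l <- embed_pca(ml, genes = intersect(hvg, colnames(ml$counts)), n_pcs = n_pcs)
  pt <- diffusion_pseudotime(pca_l, root = root, k = k, n_comps = n_comps)
  lineage_scores <- dplyr::semi_join(scores, ml$obs, by = "barcode")
  curve <- bin_curve(lineage_scores, pt, n_bins = n_bins)
  fit <- polyfit_curve(curve, degree = poly_degree)

  comparisons <- .pathway_pair_comparisons(lineage_scores)

  bundle <- list(matrix = m, clusters = clusters, markers = markers,
                 labels = labels, scores = scores, pseudotime = pt,
                 curve = curve, fit = fit, comparisons = comparisons, log = log)
  if (!is.null(out_dir)) .write_sc_bundle(bundle, out_dir)
  bundle
}

# all pairwise DSB pathway contrasts on non-excluded cells (unpaired; the
# cells entering each pathway's vector differ after zero-exclusion)
.pathway_pair_comparisons <- function(scores) {
  s <- dplyr::filter(scores, !.data$excluded)
  pws <- unique(s$set_name)
  out <- list()
  for (i in seq_along(pws)) for (j in seq_along(pws)) {
    if (i >= j) next
    cmp <- compare_scores(list(
      a = s$score[s$set_name == pws[i]],
      b = s$score[s$set_name == pws[j]]))
    row <- tidy(cmp)
    row$group1 <- pws[i]; row$group2 <- pws[j]
    out[[length(out) + 1L]] <- row
  }
  dplyr::bind_rows(out)
}

.write_sc_bundle <- function(b, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(d, f) write.table(d, file.path(out_dir, f), sep = "\t",
                                  quote = FALSE, row.names = FALSE)
  cl <- dplyr::left_join(
    dplyr::select(b$matrix$obs, "barcode", "batch", "cluster", "label"),
    b$labels[c("cluster", "overlap_score")],
    by = c("cluster"))
  w(cl, "clusters.tsv")
  w(b$markers, "markers.tsv")
  sw <- dplyr::left_join(scores_wide(b$scores), b$pseudotime, by = "barcode")
  w(sw, "scores.tsv")
  w(b$curve, "curve.tsv")
  jsonlite::write_json(
    list(fit = split(b$fit$coefficient, b$fit$set_name),
         comparisons = b$comparisons, log = b$log),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(out_dir)
}

#' Cross-species bulk comparison analysis
#'
#' Per species: quantile normalization across replicates, log2(x+1)
#' transform, pathway annotation; then replicate-paired Wilcoxon signed-rank
#' contrasts per species and a DSB-gene PCA/Spearman across all samples.
#' Species with a single replicate skip testing with a warning but still
#' enter the correlation.
#'
#' @param tables Named list of [bulk_table()]s, one per species.
#' @param out_dir Optional output directory.
#' @return List bundle: `pathway_table`, `tests`, `pca_spearman`, `log`.
#' @export
run_species_compare <- function(tables, out_dir = NULL) {
  norm <- lapply(tables, function(t) log_tpm(quantile_normalize(t)))
  pl <- pathway_long_bind(norm)
  testable <- names(norm)[vapply(norm, function(t) ncol(t$values) >= 2, TRUE)]
  skipped <- setdiff(names(norm), testable)
  if (length(skipped)) {
    warn(sprintf("species with one replicate skipped in testing: %s",
                 paste(skipped, collapse = ", ")))
  }
  tests <- if (length(testable)) {
    pairwise_pathway_tests(pl, species = testable)
  } else tibble()
  ps <- dsb_pca_spearman(norm)
  log <- list(species = names(tables),
              replicates = vapply(tables, function(t) ncol(t$values), 0L),
              pairing = "replicate-level pathway means",
              n_dsb_genes = length(ps$genes))
  bundle <- list(pathway_table = pl, tests = tests, pca_spearman = ps, log = log)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.table(pl, file.path(out_dir, "pathway_long.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(data.frame(sample = rownames(ps$spearman), ps$spearman,
                           check.names = FALSE),
                file.path(out_dir, "spearman.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(tests = tests, log = log),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  bundle
}

#' Bulk time-course analysis
#'
#' log2(x+1) transform followed by per-day gene-set summaries (DSB pathways
#' plus the G2/M cell-cycle set).
#'
#' @param t A [bulk_table()] with `day` metadata (TPM scale).
#' @param species Symbol nomenclature of the table.
#' @param out_dir Optional output directory.
#' @return List bundle: `summary` (tibble), `log`.
#' @export
run_bulk_timecourse <- function(t, species = "human", out_dir = NULL) {
  lt <- log_tpm(t)
  sets <- c(load_dsb_sets(species), cell_cycle_sets(species)["G2M"])
  s <- timecourse_summary(lt, sets)
  bundle <- list(summary = s,
                 log = list(species = species, days = sort(unique(t$samples$day)),
                            transform = "log2(TPM + 1)"))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.table(s, file.path(out_dir, "timecourse.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(bundle$log, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  bundle
}
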