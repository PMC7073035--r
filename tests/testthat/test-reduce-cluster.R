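test_that("HVG selection finds planted high-dispersion genes", {
  withr::with_seed(11, {
    n <- 200
    base <- matrix(rpois(n * 20, 5), n, 20)
    hot <- cbind(rnbinom(n, mu = 5, size = 0.3),
                 rnbinom(n, mu = 5, size = 0.3),
                 rnbinom(n, mu = 5, size = 0.3))
    counts <- cbind(base, hot)
    colnames(counts) <- c(paste0("flat", 1:20), paste0("hot", 1:3))
    rownames(counts) <- paste0("c", seq_len(n))
  })
  m <- normalize_log(cell_matrix(counts))
  top3 <- select_common_hvg(m, n_per_batch = 3)
  expect_setequal(top3, paste0("hot", 1:3))
})

test_that("constant genes are never selected and batch intersection is symmetric", {
  counts <- dense_counts(60, paste0("g", 1:30), seed = 12)
  counts[, "g1"] <- 3L  # constant
  m <- cell_matrix(counts)
  m$obs$batch <- rep(c("b1", "b2"), each = 30)
  # make the two batches identical so intersection equals either top list
  m$counts[31:60, ] <- m$counts[1:30, ]
  m <- normalize_log(m)
  hv <- select_common_hvg(m, n_per_batch = 10)
  expect_false("g1" %in% hv)
  expect_length(hv, 10)
  hv_t <- select_common_hvg(m, n_per_batch = 10, n_target = 5)
  expect_length(hv_t, 5)
  expect_true(all(hv_t %in% hv))
})

test_that("PCA matches covariance eigendecomposition up to sign", {
  counts <- dense_counts(30, paste0("g", 1:8), seed = 13)
  m <- normalize_log(cell_matrix(counts))
  p <- embed_pca(m, n_pcs = 4)
  x <- as.matrix(m$layers$lognorm)
  xc <- scale(x, center = TRUE, scale = FALSE)
  ev <- eigen(crossprod(xc) / (nrow(xc) - 1), symmetric = TRUE)
  oracle <- xc %*% ev$vectors[, 1:4]
  for (j in 1:4) {
    expect_equal(abs(cor(p$coords[, j], oracle[, j])), 1, tolerance = 1e-8)
  }
  expect_equal(p$var_explained,
               (ev$values / sum(ev$values))[1:4], tolerance = 1e-8)
  # variance fractions non-increasing, sum <= 1; loadings orthogonal by construction
  expect_true(all(diff(p$var_explained) <= 1e-12))
  expect_lte(sum(p$var_explained), 1 + 1e-12)
  # colinear points: PC1 captures everything
  line <- cell_matrix(matrix(as.integer(outer(0:9, c(1, 2))), 10, 2,
                             dimnames = list(paste0("c", 1:10), c("a", "b"))))
  pl <- embed_pca(normalize_log(line, target_sum = 10), n_pcs = 2)
  expect_gt(pl$var_explained[1], 0.99)
  expect_warning(embed_pca(m, n_pcs = 100), "clipped")
})

test_that("kNN graph matches brute-force neighbors and connects blobs", {
  withr::with_seed(14, {
    coords <- matrix(rnorm(120 * 3), 120, 3)
    rownames(coords) <- paste0("c", 1:120)
  })
  g <- knn_graph(coords, k = 5)
  d <- as.matrix(dist(coords))
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  for (i in seq_len(nrow(coords))) {
    nb <- order(d[i, ])[2:6]
    expect_true(all(adj[i, nb] > 0))  # own neighbors always present (union)
  }
  expect_equal(igraph::components(g)$no, 1)  # dense blob is connected at k=5
  # middle of 3 collinear points connects to both ends after symmetrization
  tri <- matrix(c(0, 1, 2), 3, 1, dimnames = list(c("a", "b", "c"), NULL))
  gt <- knn_graph(tri, k = 1)
  expect_equal(igraph::degree(gt)["b"], c(b = 2))
})

test_that("community detection recovers two planted blobs, deterministically", {
  withr::with_seed(15, {
    coords <- rbind(matrix(rnorm(80 * 2), 80, 2),
                    matrix(rnorm(80 * 2, mean = 12), 80, 2))
    rownames(coords) <- paste0("c", 1:160)
  })
  g <- knn_graph(coords, k = 10)
  blob <- rep(c("b1", "b2"), each = 80)
  for (alg in c("louvain", "leiden")) {
    cl <- cluster_graph(g, seed = 0, algorithm = alg)
    expect_equal(nrow(cl), 160)
    expect_false(anyNA(cl$cluster))
    # no community ever straddles the two blobs (perfect planted purity)
    purity <- table(cl$cluster, blob)
    expect_true(all(apply(purity, 1, min) == 0))
    # at coarse resolution the planted two-blob partition is recovered exactly
    cl_lo <- cluster_graph(g, resolution = 0.05, seed = 0, algorithm = alg)
    expect_equal(length(unique(cl_lo$cluster)), 2)
    expect_equal(length(unique(cl_lo$cluster[1:80])), 1)
    expect_equal(length(unique(cl_lo$cluster[81:160])), 1)
    cl2 <- cluster_graph(g, seed = 0, algorithm = alg)
    expect_identical(cl$cluster, cl2$cluster)
  }
})

test_that("marker t-statistics match the Welch formula and rank planted markers first", {
  counts <- dense_counts(40, paste0("g", 1:5), seed = 16)
  counts[, "g5"] <- 1L                       # near-constant
  counts[1:20, "g1"] <- counts[1:20, "g1"] + 20L  # planted marker of cluster A
  m <- normalize_log(cell_matrix(counts))
  clusters <- tibble::tibble(barcode = rownames(counts),
                             cluster = rep(c("A", "B"), each = 20))
  mk <- suppressWarnings(rank_markers_ttest(m, clusters, top_n = 5))
  a <- mk[mk$cluster == "A", ]
  expect_equal(a$gene[1], "g1")
  # oracle: t.test per gene on the log layer
  x <- as.matrix(m$layers$lognorm)
  for (i in seq_len(nrow(a))) {
    tt <- t.test(x[1:20, a$gene[i]], x[21:40, a$gene[i]])
    expect_equal(a$t[i], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(a$p_value[i], tt$p.value, tolerance = 1e-10)
  }
  # identical-across-cells gene never appears
  counts2 <- counts; counts2[, ] <- 2L
  m2 <- normalize_log(cell_matrix(counts2))
  mk2 <- rank_markers_ttest(m2, clusters, top_n = 5)
  expect_equal(nrow(mk2), 0)
  # tiny cluster skipped with warning
  cl3 <- tibble::tibble(barcode = rownames(counts),
                        cluster = c(rep("A", 38), "B", "B"))
  expect_warning(rank_markers_ttest(m, cl3), "too few cells")
})

test_that("overlap annotation scores, ties and unassigned fall out correctly", {
  ref <- list(
    rod = gene_set("rod", "MARKER", "human", c("RHO", "GNAT1", "NRL")),
    cone = gene_set("cone", "MARKER", "human", c("ARR3", "GNAT2", "PDE6H"))
  )
  mk <- tibble::tibble(
    cluster = rep(c("0", "1", "2"), each = 3),
    rank = rep(1:3, 3),
    gene = c("RHO", "GNAT1", "NRL",     # exact rod match
             "ARR3", "GNAT2", "XXX",    # partial cone
             "AAA", "BBB", "CCC"),      # nothing
    t = rep(3:1, 3), p_value = rep(0.01, 9))
  class(mk) <- c("marker_table", class(mk))
  lab <- annotate_clusters_overlap(mk, ref)
  expect_equal(lab$label, c("rod", "cone", "unassigned"))
  expect_equal(lab$overlap_score, c(1, 2 / 3, 0), ignore_attr = TRUE)
  expect_equal(lab$runner_up[1], "cone")
  # tie on score resolved by larger raw intersection, then lexical order
  ref2 <- list(b_set = gene_set("b_set", "MARKER", "human", c("G1", "G2")),
               a_set = gene_set("a_set", "MARKER", "human", c("G1", "G2")))
  mk2 <- tibble::tibble(cluster = "0", rank = 1:2, gene = c("G1", "G2"),
                        t = 2:1, p_value = c(0.1, 0.1))
  lab2 <- annotate_clusters_overlap(mk2, ref2)
  expect_equal(lab2$label, "a_set")
})
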