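test_that("log_tpm is elementwise log2(x + 1)", {
  v <- matrix(c(0, 3, 7, 1), 2, 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
  t <- bulk_table(v, tibble::tibble(sample = c("s1", "s2"), species = "human"))
  lt <- log_tpm(t)
  expect_equal(lt$values, log2(v + 1))
  expect_equal(lt$values["g1", "s1"], 0)
  expect_equal(lt$values["g2", "s1"], 2)    # log2(4)
  expect_identical(lt$samples, t$samples)
})

test_that("quantile normalization has the defining property and known small case", {
  v <- matrix(c(2, 4, 6, 1, 2, 3), 3, 2,
              dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  t <- bulk_table(v, tibble::tibble(sample = c("s1", "s2"), species = "human"))
  qn <- quantile_normalize(t)
  expect_equal(unname(qn$values[, 1]), c(1.5, 3, 4.5))
  expect_equal(unname(qn$values[, 2]), c(1.5, 3, 4.5))
  # defining property + idempotence + pooled-mean preservation on random fixtures
  for (seed in 1:10) {
    x <- withr::with_seed(seed, matrix(rlnorm(40 * 4), 40, 4,
      dimnames = list(paste0("g", 1:40), paste0("s", 1:4))))
    tt <- bulk_table(x, tibble::tibble(sample = paste0("s", 1:4), species = "human"))
    q1 <- quantile_normalize(tt)
    sorted <- apply(q1$values, 2, sort)
    for (j in 2:4) expect_equal(sorted[, j], sorted[, 1], tolerance = 1e-12)
    q2 <- quantile_normalize(q1)
    expect_equal(q2$values, q1$values, tolerance = 1e-12)
    expect_equal(mean(q1$values), mean(x), tolerance = 1e-12)
  }
})

test_that("tie handling matches the enumeration oracle and limma agrees when tie-free", {
  for (seed in 1:10) {
    x <- withr::with_seed(seed, matrix(rpois(30 * 3, 3), 30, 3,   # many ties
      dimnames = list(paste0("g", 1:30), paste0("s", 1:3))))
    tt <- bulk_table(x, tibble::tibble(sample = paste0("s", 1:3), species = "human"))
    qn <- quantile_normalize(tt)
    expect_equal(qn$values, enumerate_quantile_norm(x), tolerance = 1e-12)
  }
  skip_if_not_installed("limma")
  x <- withr::with_seed(99, matrix(rlnorm(50 * 4), 50, 4,
    dimnames = list(paste0("g", 1:50), paste0("s", 1:4))))
  tt <- bulk_table(x, tibble::tibble(sample = paste0("s", 1:4), species = "human"))
  qn <- quantile_normalize(tt)
  expect_equal(unname(qn$values), unname(limma::normalizeQuantiles(x)),
               tolerance = 1e-8)
})

test_that("grouped normalization respects groups; singletons pass through", {
  x <- matrix(rlnorm(20 * 3), 20, 3,
              dimnames = list(paste0("g", 1:20), c("h1", "h2", "m1")))
  t <- bulk_table(x, tibble::tibble(sample = c("h1", "h2", "m1"),
                                    species = c("human", "human", "mouse")))
  expect_warning(qn <- quantile_normalize(t), "single sample")
  expect_equal(sort(qn$values[, "h1"]), sort(qn$values[, "h2"]),
               ignore_attr = TRUE)
  expect_equal(qn$values[, "m1"], x[, "m1"])
})

test_that("pathway long table counts genes per sample and flags absences", {
  genes <- human_dsb_symbols()
  x <- matrix(rlnorm(17 * 2), 17, 2, dimnames = list(genes, c("s1", "s2")))
  t <- bulk_table(x, tibble::tibble(sample = c("s1", "s2"), species = "human",
                                    replicate = 1:2))
  pl <- build_pathway_table(t)
  expect_equal(nrow(pl), 34)  # 17 genes x 2 samples
  expect_equal(sum(pl$pathway == "HDR"), 16)
  # macaque table missing EXO1 -> 7 HDR rows per sample, logged not fatal
  x2 <- x[setdiff(genes, "EXO1"), , drop = FALSE]
  t2 <- bulk_table(x2, tibble::tibble(sample = c("s1", "s2"), species = "macaque"))
  expect_message(pl2 <- build_pathway_table(t2), "EXO1")
  expect_equal(sum(pl2$pathway == "HDR" & pl2$sample == "s1"), 7)
  # row count equals sum over samples of genes present
  expect_equal(nrow(pl2), 2 * 16)
  # a pathway with nothing present errors with species and pathway named
  x3 <- x[1:4, , drop = FALSE]  # NHEJ only
  t3 <- bulk_table(x3, tibble::tibble(sample = c("s1", "s2"), species = "human"))
  expect_error(build_pathway_table(t3), class = "dsbscore_missing_gene_set")
})

test_that("timecourse summary equals a loop oracle and flags single replicates", {
  genes <- c(human_dsb_symbols(), "ACTB")
  days <- c(0, 2, 4)
  samples <- tibble::tibble(sample = paste0("s", 1:6), species = "human",
                            day = rep(days, each = 2), replicate = rep(1:2, 3))
  x <- withr::with_seed(7, matrix(rlnorm(length(genes) * 6), length(genes), 6,
                                  dimnames = list(genes, samples$sample)))
  t <- bulk_table(x, samples)
  sets <- load_dsb_sets("human")["HDR"]
  s <- timecourse_summary(t, sets)
  expect_equal(nrow(s), 3)
  for (i in seq_along(days)) {
    v <- as.vector(x[set_symbols(sets$HDR), samples$day == days[i]])
    expect_equal(s$mean[i], mean(v), tolerance = 1e-12)
    expect_equal(s$ci_hi[i] - s$mean[i], 1.96 * sd(v) / sqrt(length(v)),
                 tolerance = 1e-12)
  }
  t1 <- bulk_table(x[, 1, drop = FALSE],
                   tibble::tibble(sample = "s1", species = "human", day = 0))
  s1 <- timecourse_summary(t1, sets)
  expect_equal(s1$ci_over, "genes")
})

test_that("DSB PCA/Spearman has unit diagonal, symmetry and exact small cases", {
  genes <- human_dsb_symbols()
  x <- withr::with_seed(8, matrix(rlnorm(17 * 3), 17, 3,
                                  dimnames = list(genes, c("a", "b", "dup"))))
  x[, "dup"] <- x[, "a"]  # duplicated sample
  t <- bulk_table(x, tibble::tibble(sample = c("a", "b", "dup"), species = "human"))
  ps <- dsb_pca_spearman(list(t))
  expect_equal(ps$spearman, t(ps$spearman))
  expect_equal(unname(diag(ps$spearman)), rep(1, 3))
  expect_equal(ps$spearman["a", "dup"], 1)
  # antithetic vectors give Spearman -1
  y <- matrix(c(1, 2, 3, 3, 2, 1), 3, 2,
              dimnames = list(c("BRCA1", "BRCA2", "RAD51"), c("u", "v")))
  t2 <- bulk_table(y, tibble::tibble(sample = c("u", "v"), species = "human"))
  ps2 <- suppressMessages(dsb_pca_spearman(list(t2)))
  expect_equal(ps2$spearman["u", "v"], -1)
  expect_error(dsb_pca_spearman(list(bulk_table(
    matrix(1, 2, 2, dimnames = list(c("BRCA1", "BRCA2"), c("x", "y"))),
    tibble::tibble(sample = c("x", "y"), species = "human")))),
    "fewer than 3")
})

test_that("pathway annotation accepts native and ortholog-mapped symbol tables", {
  genes_hu <- human_dsb_symbols()
  x <- withr::with_seed(61, matrix(rlnorm(17 * 2), 17, 2,
                                   dimnames = list(genes_hu, c("m1", "m2"))))
  # mouse-species table carrying human-style (ortholog-mapped) symbols
  t_map <- bulk_table(x, tibble::tibble(sample = c("m1", "m2"), species = "mouse"))
  pl_map <- build_pathway_table(t_map)
  expect_equal(nrow(pl_map), 34)
  # the same table in native mouse nomenclature gives the same structure
  x2 <- x
  rownames(x2) <- map_symbol(genes_hu, symbol_map("human", "mouse"))
  t_nat <- bulk_table(x2, tibble::tibble(sample = c("m1", "m2"), species = "mouse"))
  pl_nat <- build_pathway_table(t_nat)
  expect_equal(pl_nat$pathway, pl_map$pathway)
  expect_equal(pl_nat$expr, pl_map$expr)
})
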