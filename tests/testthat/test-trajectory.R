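test_that("lineage subsetting keeps exactly the requested labels and layers", {
  sim <- simulate_sc_trajectory(
    sim_config(seed = 4, n_cells = c(progenitor = 30, neuroblast = 20, rod = 20)))
  m <- normalize_log(sim$matrix)
  m$obs$cluster <- sim$truth$true_type
  sub <- subset_lineage(m, c("progenitor", "rod"))
  expect_setequal(unique(sub$obs$cluster), c("progenitor", "rod"))
  expect_equal(n_cells(sub), 50)
  expect_equal(nrow(sub$layers$lognorm), 50)
  # set-membership oracle
  expect_setequal(sub$obs$barcode,
                  m$obs$barcode[m$obs$cluster %in% c("progenitor", "rod")])
  # keep-all is the identity
  all3 <- subset_lineage(m, c("progenitor", "neuroblast", "rod"))
  expect_identical(all3$obs$barcode, m$obs$barcode)
  expect_error(subset_lineage(m, "muller"), "not present")
})

test_that("root selection maximizes the criterion with a lexical tie-break", {
  m <- cell_matrix(matrix(1L, 4, 2, dimnames = list(c("d", "c", "b", "a"), c("g1", "g2"))))
  m$obs$score_G2M <- c(1, 5, 5, 2)
  m$obs$cluster <- c("p", "p", "p", "q")
  expect_equal(select_root(m), "b")   # ties: lexicographically first barcode
  m$obs$score_G2M <- c(1, 2, 3, 9)
  expect_equal(select_root(m), "a")
  expect_equal(select_root(m, within = "p"), "b")
  expect_error(select_root(m, criterion = "nope"), "not found")
})

test_that("pseudotime orders a 1D segment and is zero at the root", {
  coords <- matrix(seq(0, 29), 30, 1, dimnames = list(sprintf("c%02d", 1:30), NULL))
  pt <- diffusion_pseudotime(coords, root = "c01", k = 5, n_comps = 5)
  expect_equal(pt$pseudotime[1], 0)
  expect_true(all(diff(pt$pseudotime) > 0))  # strictly increasing with position
  expect_true(all(pt$finite))
})

test_that("transition eigen-system matches a dense independent decomposition", {
  withr::with_seed(41, {
    coords <- matrix(rnorm(80 * 3), 80, 3)
    rownames(coords) <- sprintf("c%02d", 1:80)
  })
  k <- 10; n_comps <- 6
  pt <- diffusion_pseudotime(coords, root = "c01", k = k, n_comps = n_comps)
  vals <- attr(pt, "eigenvalues")
  vecs <- attr(pt, "eigenvectors")
  # oracle: build the kernel and Markov matrix from scratch, non-symmetric eigen
  d <- as.matrix(dist(coords))
  n <- nrow(d)
  nb <- t(apply(d, 1, function(r) order(r)[2:(k + 1)]))
  sigma <- vapply(1:n, function(i) d[i, nb[i, ceiling(k / 2)]], 0)
  K <- matrix(0, n, n)
  for (i in 1:n) K[i, nb[i, ]] <- exp(-d[i, nb[i, ]]^2 / (sigma[i] * sigma[nb[i, ]]))
  K <- pmax(K, t(K)); diag(K) <- 1
  q <- rowSums(K); W <- K / outer(q, q); P <- W / rowSums(W)
  e <- eigen(P)
  ord <- order(-Re(e$values))
  vals_oracle <- Re(e$values[ord])[seq_len(n_comps + 1)]
  expect_equal(vals[-1], vals_oracle[-1], tolerance = 1e-8)
  expect_equal(vals_oracle[1], 1, tolerance = 1e-10)
  # eigenvectors parallel to oracle right eigenvectors (up to sign/scale)
  for (j in 2:(n_comps + 1)) {
    v_o <- Re(e$vectors[, ord[j]])
    expect_equal(abs(cor(vecs[, j], v_o)), 1, tolerance = 1e-6)
  }
})

test_that("pseudotime is invariant to rigid rotation of the embedding", {
  withr::with_seed(42, {
    coords <- matrix(rnorm(60 * 2), 60, 2)
    rownames(coords) <- sprintf("c%02d", 1:60)
    theta <- runif(1, 0, 2 * pi)
  })
  rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  pt1 <- diffusion_pseudotime(coords, root = "c01", k = 8, n_comps = 5)
  pt2 <- diffusion_pseudotime(coords %*% rot, root = "c01", k = 8, n_comps = 5)
  expect_equal(pt1$pseudotime, pt2$pseudotime, tolerance = 1e-8)
})

test_that("disconnected cells get infinite pseudotime and leave the curves", {
  coords <- rbind(matrix(seq(0, 19) / 2, 20, 1),
                  matrix(seq(0, 9) + 1000, 10, 1))
  rownames(coords) <- sprintf("c%02d", 1:30)
  expect_warning(
    pt <- diffusion_pseudotime(coords, root = "c01", k = 3, n_comps = 3),
    "disconnected")
  expect_true(all(is.infinite(pt$pseudotime[21:30])))
  scores <- tibble::tibble(barcode = rownames(coords), set_name = "NHEJ",
                           pathway = "NHEJ", score = 1, excluded = FALSE)
  cu <- bin_curve(scores, pt, n_bins = 4)
  expect_equal(sum(cu$n), 20)  # only the root component contributes
})

test_that("bin means and CIs match a loop oracle; constant scores give zero CI", {
  withr::with_seed(43, {
    n <- 100
    pt_raw <- runif(n)
    sc <- rpois(n, 5)
  })
  pt <- tibble::tibble(barcode = sprintf("c%03d", 1:n), pseudotime = pt_raw,
                       finite = TRUE)
  class(pt) <- c("pseudotime_result", class(pt))
  scores <- tibble::tibble(barcode = pt$barcode, set_name = "HDR",
                           pathway = "HDR", score = as.numeric(sc),
                           excluded = FALSE)
  cu <- bin_curve(scores, pt, n_bins = 5)
  expect_equal(nrow(cu), 5)
  expect_equal(sum(cu$n), n)
  # oracle: sort by pseudotime, split into 5 consecutive blocks of 20
  ord <- order(pt_raw)
  for (b in 1:5) {
    idx <- ord[((b - 1) * 20 + 1):(b * 20)]
    expect_equal(cu$mean[b], mean(sc[idx]), tolerance = 1e-12)
    half <- 1.96 * sd(sc[idx]) / sqrt(20)
    expect_equal(cu$ci_hi[b] - cu$mean[b], half, tolerance = 1e-12)
  }
  # pooled mean is invariant to the binning resolution
  cu10 <- bin_curve(scores, pt, n_bins = 10)
  expect_equal(sum(cu$n * cu$mean) / sum(cu$n),
               sum(cu10$n * cu10$mean) / sum(cu10$n), tolerance = 1e-12)
  const <- dplyr::mutate(scores, score = 5)
  cuc <- bin_curve(const, pt, n_bins = 4)
  expect_true(all(cuc$mean == 5))
  expect_true(all(cuc$ci_hi - cuc$ci_lo == 0))
})

test_that("polynomial fits match the normal equations and recover exact lines", {
  cu <- tibble::tibble(set_name = "HDR", pathway = "HDR", bin = 1:10,
                       midpoint = seq(0.05, 0.95, length.out = 10),
                       n = 10, mean = 2 - 1.5 * seq(0.05, 0.95, length.out = 10),
                       ci_lo = NA, ci_hi = NA)
  class(cu) <- c("trajectory_curve", class(cu))
  f1 <- polyfit_curve(cu, degree = 1)
  expect_equal(f1$coefficient, c(2, -1.5), tolerance = 1e-10)
  expect_equal(attr(f1, "residuals")$residual_sd, 0, tolerance = 1e-10)
  f0 <- polyfit_curve(cu, degree = 0)
  expect_equal(f0$coefficient, mean(cu$mean), tolerance = 1e-12)
  # degree-3 fit equals the normal-equations solution
  withr::with_seed(44, cu$mean <- rnorm(10))
  f3 <- polyfit_curve(cu, degree = 3)
  X <- outer(cu$midpoint, 0:3, `^`)
  beta <- solve(crossprod(X), crossprod(X, cu$mean))
  expect_equal(f3$coefficient, as.numeric(beta), tolerance = 1e-8)
  pred <- predict_curve(f3, cu$midpoint)
  expect_equal(pred$fitted, as.numeric(X %*% beta), tolerance = 1e-8)
  expect_error(polyfit_curve(cu[1:3, ], degree = 3), "cannot support")
})
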