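#' Configuration of the synthetic data generator
#'
#' The generator emulates the statistical structure the analyses assume:
#' droplet UMI counts with library-size variation and dropout along a
#' progenitor -> neuroblast -> photoreceptor (cone/rod) trajectory,
#' cell-cycle-coupled HDR expression (high while cycling, collapsing at
#' cell-cycle exit), an intermediate MMEJ program, a flat NHEJ program,
#' cluster-specific marker genes drawn from the packaged retinal reference,
#' and bulk time courses / multi-species panels with the same pathway
#' structure. All randomness is fixed by `seed`.
#'
#' Pathway amplitude schedules are piecewise-linear in true time `t` in
#' \[0, 1\] (knots `t`, values `a`): HDR stays high until the cell-cycle exit
#' point `t_exit` then drops to near zero; MMEJ declines to a moderate
#' plateau; NHEJ is constant. Cell-cycle genes are on iff `t < t_exit`.
#'
#' @param seed Integer seed.
#' @param n_cells Named vector of cells per type (defaults: 500 progenitor,
#'   400 neuroblast, 300 cone, 300 rod = 1500 cells).
#' @param t_exit Cell-cycle exit point in (0, 1) (default 0.4).
#' @param amplitudes Named list of piecewise-linear schedules
#'   (`list(t = ..., a = ...)`) for HDR, MMEJ, NHEJ.
#' @param cc_amplitude Cell-cycle gene amplitude while cycling / after exit.
#' @param marker_fold Expression fold-change of a type's markers at full
#'   activation (default 15; canonical fate markers are strongly expressed).
#' @param n_background Number of inert background genes (default 300).
#' @param base_mean Baseline mean count of pathway/cycle/marker genes.
#' @param libsize_meanlog,libsize_sdlog Log-normal library-size factor.
#' @param dispersion Negative-binomial dispersion (1/size; default 0.5).
#' @param dropout Bernoulli dropout probability per count (default 0.1).
#' @param n_batches,batch_sdlog Batch count and gene-wise multiplicative
#'   log-normal batch effect scale (default: one batch, no effect).
#' @param species Symbol nomenclature of the emitted panel (default
#'   `"mouse"`, matching an embryonic mouse retina scene).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 0,
                       n_cells = c(progenitor = 500, neuroblast = 400,
                                   cone = 300, rod = 300),
                       t_exit = 0.4,
                       amplitudes = NULL,
                       cc_amplitude = c(cycling = 2.5, post = 0.05),
                       marker_fold = 15,
                       n_background = 300,
                       base_mean = 1,
                       libsize_meanlog = 0, libsize_sdlog = 0.3,
                       dispersion = 0.5,
                       dropout = 0.1,
                       n_batches = 1, batch_sdlog = 0,
                       species = "mouse") {
  if (t_exit <= 0 || t_exit >= 1) abort("t_exit must be in (0, 1)")
  if (any(n_cells < 0) || sum(n_cells) == 0) abort("need a positive number of cells")
  amplitudes <- amplitudes %||% list(
    HDR  = list(t = c(0, t_exit, t_exit + 0.15, 1), a = c(3, 3, 0.2, 0.2)),
    MMEJ = list(t = c(0, t_exit, 1),                a = c(3, 3, 1.2)),
    NHEJ = list(t = c(0, 1),                        a = c(2, 2))
  )
  for (a in amplitudes) if (any(a$a < 0)) abort("amplitudes must be >= 0")
  structure(list(
    seed = seed, n_cells = n_cells, t_exit = t_exit, amplitudes = amplitudes,
    cc_amplitude = cc_amplitude, marker_fold = marker_fold,
    n_background = n_background, base_mean = base_mean,
    libsize_meanlog = libsize_meanlog, libsize_sdlog = libsize_sdlog,
    dispersion = dispersion, dropout = dropout,
    n_batches = n_batches, batch_sdlog = batch_sdlog, species = species
  ), class = "sim_config")
}

.amp_at <- function(sched, t) {
  approx(sched$t, sched$a, xout = t, rule = 2)$y
}

# time window of each lineage type; cone/rod share the late window (branch)
.type_windows <- function(t_exit) {
  list(progenitor = c(0, t_exit),
       neuroblast = c(t_exit, 0.7),
       cone = c(0.7, 1), rod = c(0.7, 1))
}

# smooth activation of a type's markers as a function of (t, type)
.marker_activation <- function(type, t, true_type, t_exit) {
  switch(type,
    progenitor = 1 / (1 + exp((t - t_exit) / 0.05)),
    neuroblast = exp(-(t - (t_exit + 0.7) / 2)^2 / (2 * 0.12^2)),
    cone = ifelse(true_type == "cone", pmin(1, pmax(0, (t - 0.7) / 0.05)), 0),
    rod  = ifelse(true_type == "rod",  pmin(1, pmax(0, (t - 0.7) / 0.05)), 0)
  )
}

#' Simulate a single-cell differentiation trajectory
#'
#' Draws per-cell true times within each type's window, builds gene-wise mean
#' expression (baseline x marker activation x pathway amplitude), multiplies
#' by a log-normal library-size factor, and emits negative-binomial counts
#' thinned by Bernoulli dropout. The panel comprises the 17 curated DSB
#' genes, the packaged cell-cycle sets (on only while cycling), type markers
#' drawn from the packaged retinal reference, ten monotone neuronal
#' maturation genes, and inert background genes. Deterministic given the
#' config seed.
#'
#' @param cfg A [sim_config()].
#' @return List with `matrix` (a [cell_matrix()]) and `truth` (tibble:
#'   `barcode`, `true_time`, `true_type`, `batch`, `cycling`).
#' @export
simulate_sc_trajectory <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, .simulate_sc(cfg))
}

.simulate_sc <- function(cfg) {
  types <- names(cfg$n_cells)
  windows <- .type_windows(cfg$t_exit)
  unknown <- setdiff(types, names(windows))
  if (length(unknown)) abort(sprintf("unknown cell types: %s", paste(unknown, collapse = ", ")))
  true_type <- rep(types, cfg$n_cells)
  n <- length(true_type)
  t <- vapply(true_type, function(ty) runif(1, windows[[ty]][1], windows[[ty]][2]), 0)
  ord <- order(t)
  t <- t[ord]; true_type <- true_type[ord]
  barcode <- sprintf("cell%05d", seq_len(n))
  cycling <- t < cfg$t_exit
  batch <- paste0("batch", rep_len(seq_len(cfg$n_batches), n))

  # ---- gene panel -----------------------------------------------------------
  dsb <- load_dsb_sets(cfg$species)
  cc <- cell_cycle_sets(cfg$species)
  markers <- retinal_marker_sets(cfg$species)[c("progenitor", "neuroblast", "cone", "rod")]
  maturation <- map_symbol(
    c("TUBB3", "MAP2", "SNAP25", "SYT1", "STMN2", "DCX", "ELAVL3",
      "NSG1", "SYP", "NEFM"),
    symbol_map("human", cfg$species))
  background <- sprintf("BG%04d", seq_len(cfg$n_background))
  panel <- c(unlist(lapply(dsb, set_symbols)),
             unlist(lapply(cc, set_symbols)),
             unlist(lapply(markers, set_symbols)),
             maturation, background)
  panel <- unname(panel)
  g <- length(panel)

  # ---- mean model -----------------------------------------------------------
  mu <- matrix(0, n, g, dimnames = list(barcode, panel))
  for (pw in names(dsb)) {
    amp <- .amp_at(cfg$amplitudes[[pw]], t)
    mu[, set_symbols(dsb[[pw]])] <- cfg$base_mean * amp
  }
  # proliferative intensity wanes as progenitors approach terminal division,
  # so the strongest cycle signal sits at the trajectory start
  cc_amp <- ifelse(cycling,
                   cfg$cc_amplitude[["cycling"]] * (1 - 0.7 * t / cfg$t_exit),
                   cfg$cc_amplitude[["post"]])
  for (ph in names(cc)) mu[, set_symbols(cc[[ph]])] <- cfg$base_mean * cc_amp
  for (ty in names(markers)) {
    act <- .marker_activation(ty, t, true_type, cfg$t_exit)
    mu[, set_symbols(markers[[ty]])] <-
      cfg$base_mean * 0.3 * (1 + (cfg$marker_fold - 1) * act)
  }
  mu[, maturation] <- cfg$base_mean * 0.3 * (1 + (cfg$marker_fold - 1) * t^1.5)
  base_bg <- rgamma(cfg$n_background, shape = 2, rate = 4)  # mean 0.5
  mu[, background] <- matrix(base_bg, n, cfg$n_background, byrow = TRUE)

  if (cfg$batch_sdlog > 0) {
    for (b in unique(batch)) {
      eff <- rlnorm(g, 0, cfg$batch_sdlog)
      mu[batch == b, ] <- sweep(mu[batch == b, , drop = FALSE], 2, eff, `*`)
    }
  }
  lib <- rlnorm(n, cfg$libsize_meanlog, cfg$libsize_sdlog)
  mu <- mu * lib

  # ---- counts ---------------------------------------------------------------
  counts <- matrix(rnbinom(n * g, mu = as.vector(mu), size = 1 / cfg$dispersion),
                   n, g, dimnames = dimnames(mu))
  if (cfg$dropout > 0) {
    keep <- matrix(rbinom(n * g, 1, 1 - cfg$dropout), n, g)
    counts <- counts * keep
  }
  truth <- tibble(barcode = barcode, true_time = t, true_type = true_type,
                  batch = batch, cycling = cycling)
  m <- cell_matrix(counts, obs = truth["barcode"], batch = batch)
  list(matrix = m, truth = truth)
}

#' Simulate a bulk differentiation time course
#'
#' Per time point the pathway mean interpolates between its cycling and
#' postmitotic level according to a cycling fraction that decays linearly to
#' zero at `cycle_off_day` (emulating a culture exiting the cell cycle);
#' replicate noise is multiplicative log-normal, and columns are TPM-scaled
#' (sum 1e6).
#'
#' @param cfg A [sim_config()] (`seed`, `dispersion` unused here; amplitude
#'   endpoints reuse the single-cell schedules at t = 0 and t = 1).
#' @param days Numeric vector of time points (days; >= 2 required).
#' @param replicates Replicates per time point (default 3).
#' @param cycle_off_day Day by which the cycling fraction reaches 0
#'   (default 4).
#' @param noise_sdlog Replicate log-normal noise (default 0.15).
#' @return List with `table` (a [bulk_table()], human symbols) and `truth`
#'   (tibble of per-day pathway means and cycling fractions).
#' @export
simulate_bulk_timecourse <- function(cfg = sim_config(species = "human"),
                                     days = c(0, 1, 2, 3, 4, 7, 14),
                                     replicates = 3, cycle_off_day = 4,
                                     noise_sdlog = 0.15) {
  if (length(days) < 2L) abort("need >= 2 time points")
  withr::with_seed(cfg$seed, {
    dsb <- load_dsb_sets("human")
    g2m <- cell_cycle_sets("human")$G2M
    background <- sprintf("BG%04d", seq_len(100))
    base_bg <- rgamma(100, shape = 2, rate = 2)
    frac <- pmax(0, 1 - days / cycle_off_day)
    level <- function(pw) {
      a <- cfg$amplitudes[[pw]]
      c(cyc = .amp_at(a, 0), post = .amp_at(a, 1))
    }
    truth <- list(); cols <- list(); meta <- list()
    for (i in seq_along(days)) {
      mean_pw <- vapply(names(dsb), function(pw) {
        lv <- level(pw); lv[["cyc"]] * frac[i] + lv[["post"]] * (1 - frac[i])
      }, 0)
      cc_mean <- cfg$cc_amplitude[["cycling"]] * frac[i] +
        cfg$cc_amplitude[["post"]] * (1 - frac[i])
      truth[[i]] <- tibble(day = days[i], cycling_fraction = frac[i],
                           pathway = c(names(mean_pw), "G2M"),
                           mean_level = c(mean_pw, cc_mean))
      for (r in seq_len(replicates)) {
        v <- c(unlist(lapply(names(dsb), function(pw)
          setNames(rep(mean_pw[[pw]], length(dsb[[pw]])), set_symbols(dsb[[pw]])))),
          setNames(rep(cc_mean, length(g2m)), set_symbols(g2m)),
          setNames(base_bg, background))
        v <- v * rlnorm(length(v), 0, noise_sdlog)
        cols[[length(cols) + 1L]] <- v * 1e6 / sum(v)
        meta[[length(meta) + 1L]] <- tibble(
          sample = sprintf("d%g_r%d", days[i], r), species = "human",
          condition = "timecourse", day = days[i], replicate = r)
      }
    }
    values <- do.call(cbind, cols)
    samples <- dplyr::bind_rows(meta)
    colnames(values) <- samples$sample
    list(table = bulk_table(values, samples), truth = dplyr::bind_rows(truth))
  })
}

#' Simulate a multi-species bulk retina panel
#'
#' Each species gets a configurable pathway mean profile (defaults: human,
#' macaque and mouse express NHEJ > MMEJ > HDR; the squirrel-like profile has
#' NHEJ and MMEJ at the same level), replicate noise is log-normal and
#' columns are TPM-scaled.
#'
#' @param cfg A [sim_config()] (only `seed` is used).
#' @param species Character vector of panel species.
#' @param replicates Replicates per species (>= 2; default 6).
#' @param profiles Named list of `c(NHEJ=, MMEJ=, HDR=)` mean levels per
#'   species.
#' @param noise_sdlog Replicate log-normal noise (default 0.15).
#' @return List with `tables` (named list of [bulk_table()]s, human-style
#'   symbols) and `truth` (tibble of configured profiles).
#' @export
simulate_species_panel <- function(cfg = sim_config(species = "human"),
                                   species = c("human", "macaque", "mouse", "squirrel"),
                                   replicates = 6,
                                   profiles = NULL,
                                   noise_sdlog = 0.15) {
  if (replicates < 2L) abort("need >= 2 replicates per species")
  profiles <- profiles %||% list(
    human    = c(NHEJ = 4, MMEJ = 2, HDR = 1),
    macaque  = c(NHEJ = 4, MMEJ = 2.4, HDR = 1),
    mouse    = c(NHEJ = 4, MMEJ = 2, HDR = 1),
    squirrel = c(NHEJ = 2.2, MMEJ = 2.2, HDR = 1)
  )
  missing <- setdiff(species, names(profiles))
  if (length(missing)) abort(sprintf("no profile for: %s", paste(missing, collapse = ", ")))
  withr::with_seed(cfg$seed, {
    dsb <- load_dsb_sets("human")
    background <- sprintf("BG%04d", seq_len(100))
    base_bg <- rgamma(100, shape = 2, rate = 2)
    tables <- list()
    for (sp in species) {
      pr <- profiles[[sp]]
      cols <- list(); meta <- list()
      for (r in seq_len(replicates)) {
        v <- c(unlist(lapply(names(dsb), function(pw)
          setNames(rep(pr[[pw]], length(dsb[[pw]])), set_symbols(dsb[[pw]])))),
          setNames(base_bg, background))
        v <- v * rlnorm(length(v), 0, noise_sdlog)
        cols[[r]] <- v * 1e6 / sum(v)
        meta[[r]] <- tibble(sample = sprintf("%s_r%d", sp, r), species = sp,
                            condition = "retina", day = NA_real_, replicate = r)
      }
      values <- do.call(cbind, cols)
      samples <- dplyr::bind_rows(meta)
      colnames(values) <- samples$sample
      tables[[sp]] <- bulk_table(values, samples)
    }
    truth <- dplyr::bind_rows(lapply(species, function(sp)
      tibble(species = sp, pathway = names(profiles[[sp]]),
             mean_level = unname(profiles[[sp]]))))
    list(tables = tables, truth = truth)
  })
}
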