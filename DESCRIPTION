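Package: dsbscore
Title: Transcriptomic Scoring of Double-Strand Break Repair Pathway Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the activity of the three DNA double-strand break (DSB)
    repair pathways (non-homologous end joining, microhomology-mediated end
    joining, and homology-directed repair) from bulk and single-cell RNA-seq
    expression, using curated pathway gene sets. Provides a minimal single-cell
    chain (QC filtering, normalization, highly-variable-gene selection, PCA,
    kNN graph, modularity clustering, marker ranking and marker-overlap cluster
    annotation), per-cell pathway scoring with zero-score exclusion, diffusion
    pseudotime with binned trajectory curves and polynomial fits, bulk
    time-course and cross-species comparisons (quantile normalization, exact
    Wilcoxon signed-rank pathway contrasts, DSB-gene PCA and Spearman
    correlation), and a seeded synthetic-data generator emulating a
    progenitor-to-photoreceptor differentiation trajectory for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    igraph,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    withr,
    generics,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    limma
Config/testthat/edition: 3
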