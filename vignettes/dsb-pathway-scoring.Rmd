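---
title: "Scoring DSB repair pathway activity from transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring DSB repair pathway activity from transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsbscore)
library(dplyr)
```

## The model

A cell repairs a DNA double-strand break through one of three competing
pathways — NHEJ, MMEJ or HDR — and the choice is strongly cell-cycle
dependent: HDR needs a sister chromatid and is confined to S/G2, NHEJ runs
in every phase, MMEJ sits in between. `dsbscore` treats the mean expression
of a curated panel of pathway-determining genes as a proxy for pathway
activity:

$$\mathrm{score}(c, G) \;=\; \frac{1}{|G \cap P|}\sum_{g \in G \cap P} x_{cg}$$

where $x_{cg}$ are **raw** UMI counts (or TPM for bulk samples) and $P$ is
the gene panel of the matrix. Three modelling commitments follow from this
definition and are worth making explicit:

* **Raw counts, not normalized values.** The score is a mean over a handful
  of genes of one cell; normalizing first would mix library-size effects
  into cross-pathway contrasts within the same cell. A normalized-layer
  variant exists (`score_gene_set(..., use = "lognorm")`) for sensitivity
  analysis only.
* **Absent genes leave the denominator.** Panels differ between datasets;
  treating an absent gene as zero would penalize panel coverage, not
  activity. Each scoring call reports which genes were found.
* **Zero scores are excluded, not imputed.** In droplet scRNA-seq a small
  panel can easily drop out entirely; a score of exactly 0 is flagged and
  the cell leaves every downstream comparison for that pathway.

The curated sets are small by design (4, 5 and 8 genes): they contain the
determinant, protection and resection factors that decide pathway choice,
not every accessory protein. `RPA1`/`RPA2` sit in the HDR set with role
`SSA`, following the tabulated curation, even though RPA binding also
inhibits MMEJ — the score uses pathway membership as curated, not a
mechanistic interaction network. Mouse symbols are derived by title-casing
with exactly two true divergences (`Trp53bp1`, `Mre11a`); protein aliases
(Ku70/Ku80/CtIP) are metadata and never used for matrix lookup. Macaque and
ground-squirrel tables conventionally reuse human-style symbols, so their
maps are the identity.

The packaged cell-cycle sets (G2/M top-20-style, S) and the retinal marker
reference are **stand-ins**: conventional marker lists assembled for the
packaged defaults, shipped as `*_standin.json` and meant to be replaced by
the user's preferred lists (`read_gmt()`, `read_gene_sets_json()`).

## The single-cell chain

`run_sc_score()` chains the stages; each is exported and testable on its
own.

**QC filtering.** Boundary semantics are literal: "more than 2000 UMIs" is
strict (`> 2000`), "between 400 and 3500 genes" is inclusive. Two presets
bundle published filter sets: `e15_mouse` (UMI > 2000, 400–3500 genes) and
`organoid` (500–7000 genes, UMI < 20,000, mitochondrial fraction < 0.001).
The organoid mitochondrial ceiling of 0.1% is unusually strict — common
practice is 5–20% — but it is kept as printed; it is a plain parameter, so
any ceiling can be passed instead.

**Normalization.** Counts are scaled to 10,000 per cell and `log1p`
transformed (natural log). The raw counts layer is never mutated — scoring
reads raw counts; HVG selection, PCA and marker ranking read the log layer.

**HVG selection.** Genes are ranked per batch by normalized dispersion
(variance/mean of the log layer), z-standardized within up to 20
mean-quantile bins. The bin standard deviation is floored at 10% of the
global dispersion spread so a nearly homogeneous bin cannot turn noise into
large z-scores; the bin count shrinks for small panels. Multi-batch
selection takes the intersection of per-batch top lists, or the best
worst-case rank when a fixed list size is requested.

**Graph and clusters.** PCA (centered, 40 PCs by default) feeds a kNN graph
(k = 15, union-symmetrized, weight $1/(1+d)$, index tie-break). Community
detection optimizes modularity with either Louvain or Leiden behind one
switch (resolution 1, seeded, hence deterministic). Batch correction (MNN)
and batch-balanced kNN are deliberately not reimplemented — they are
published tools outside this package's contribution — so the graph is built
on pooled coordinates and batch mixing is only exercised on batch-free or
mild-batch synthetic scenes.

**Markers and annotation.** Per cluster, genes are ranked by the Welch
t-statistic of cluster vs rest on the log layer (top 100, upregulated
only). Cluster labels come from the overlap coefficient
$|T\cap R| / \min(|T|,|R|)$ between the top markers $T$ and each reference
set $R$; ties break by raw intersection then lexical order, and clusters
matching nothing stay `unassigned`.

## Pseudotime and curves

Diffusion pseudotime orders cells by transcriptome similarity. The kernel
is a kNN-truncated Gaussian with locally adaptive bandwidth (per-cell
bandwidth = distance to the ⌈k/2⌉-th neighbor), density-normalized and
turned into a Markov transition matrix; with nontrivial right eigenvectors
$\psi_i$ and eigenvalues $\lambda_i$, a cell's pseudotime is its Euclidean
distance from the root in the space of $\psi_i$ scaled by
$\lambda_i/(1-\lambda_i)$ (10 components by default). The eigensolve is
dense via the symmetric conjugate of the transition matrix — exact and fast
at the few-thousand-cell scale this package targets. Cells disconnected
from the root's kernel component get infinite pseudotime and leave the
curves.

The root is the cell with the maximal G2/M score within the lineage
(lexicographic tie-break): directionality comes from the biology — the
trajectory starts among actively cycling progenitors — rather than from RNA
velocity, which is out of scope.

Curves use equal-count (quantile) bins on pseudotime (20 by default) so CI
widths stay stable where cells are sparse late in the trajectory; each bin
reports mean and a normal-approximation 95% CI ($1.96\,s/\sqrt{n}$, the
simple interval matching the intended display; a bootstrap is deliberately
not the default). Polynomial fits (degree 3 by default) are plain
least-squares on (bin midpoint, bin mean) via the QR decomposition, which
also handles degree 0.

## Bulk comparisons

Bulk tables are log2(x+1)-transformed TPM (the single-cell module uses
natural log; both are fixed per module and documented). Cross-species
comparison quantile-normalizes within species first: every sample's rank-r
value becomes the mean of rank-r values across the group, and a tie group
receives the mean of all target values at the ranks it occupies — this
exact rule makes sorted vectors within a group identical and is what the
tests enforce against an enumeration oracle. Quantile normalization is
idempotent on tie-free data; with ties the group-mean rule can shift
untied samples slightly on a second pass, which is inherent to any
tie-averaging convention.

Pathway contrasts use the Wilcoxon signed-rank test with the null obtained
by **full enumeration** of all $2^n$ sign assignments when there are at
most 12 nonzero paired differences, and a tie-corrected normal
approximation with continuity correction above. The pairing unit is the
replicate-level pathway mean: pathways have unequal gene counts, so
gene-level pairing across pathways is undefined; every report records this
choice. Note the resolution limit of the exact test: with $n$ replicates
the smallest achievable two-sided p-value is $2/2^n$, so at least six
replicates are needed to reach $p < 0.05$.

Within-cell-type comparisons (`compare_scores()`) follow a normality-gated
rule: Shapiro–Wilk per group at $\alpha = 0.05$; if both groups pass, a
Welch t-test (paired t if requested), otherwise a rank-based fallback. The
gate outcome is part of the result object. Whether such contrasts should be
paired (same cells, two pathway scores) is genuinely ambiguous; the driver
defaults to unpaired — after zero-score exclusion the cell sets backing two
pathways differ, so pairing is not even well-defined there — and records
the choice. Groups larger than 5000 are gated on a deterministic
evenly-spaced subsample (Shapiro–Wilk's implementation limit).

The retina-vs-in-vitro comparison merges samples on shared DSB genes, drops
zero-variance genes with a note, and reports sample-space PCA plus the full
Spearman matrix (average ranks for ties).

## The synthetic generator

Real datasets behind this kind of analysis are external accessions;
`dsbscore` ships a generator so every stage is testable offline. Its
defaults define the package's reference scene:

* 1500 cells — 500 progenitors ($t \in [0, 0.4)$), 400 neuroblasts
  ($[0.4, 0.7)$), 300 cones and 300 rods ($[0.7, 1]$) — with uniform true
  times within each window; seed 0.
* Pathway programs, piecewise-linear in true time: HDR 3 → 0.2 collapsing
  just after the cell-cycle exit point $t_{exit} = 0.4$; MMEJ 3 → 1.2;
  NHEJ constant 2.
* Cell-cycle genes on only while cycling ($t < t_{exit}$), with intensity
  waning toward the exit (factor $1 - 0.7\,t/t_{exit}$) — proliferative
  activity declines as progenitors approach terminal division, which also
  places the maximal-G2/M root cell at the start of the trajectory.
* Type markers drawn from the packaged retinal reference with smooth
  activation (logistic shut-off for progenitor markers, Gaussian bump for
  neuroblast, fast post-branch ramp for rod/cone), peak fold 15 — canonical
  fate markers are strongly expressed, and the fast ramp reflects rapid
  fate commitment after the branch; ten monotone maturation genes; 300
  inert background genes.
* Counts: negative binomial (dispersion 0.5) on mean = baseline × program
  × log-normal library factor (sdlog 0.3), thinned by 10% Bernoulli
  dropout. The dropout knob is what drives the zero-score exclusion
  machinery.

What the generator does **not** emulate: ambient RNA, doublets, realistic
batch structure (batch effects exist as a gene-wise log-normal multiplier,
default off), compositional complexity of real retina, or parameters fitted
to any real dataset. Passing tests therefore demonstrate that the
implementation recovers planted structure under the stated noise model — not
performance on real data. One realistic artefact does appear in the bulk
time course: because columns are TPM-scaled, shutting down the HDR/MMEJ and
cell-cycle programs mechanically inflates the relative abundance of
everything else, so the "flat" NHEJ program shows a mild compositional rise
in log-TPM.

Problem sizes used throughout the tests and the acceptance script — the
1500-cell default scene, 150 + 150 cells for the rod/cone null, 6 replicates
per species, 20 and 50 seeded repetitions for the calibration rates — were
chosen as the smallest sizes at which the planted effects are comfortably
identifiable; they keep the full suite in the tens of seconds.

## Numerical choices and degenerate inputs

* Distance ties in kNN break by cell index; annotation ties by raw
  intersection then label order; root ties by barcode order — everything is
  deterministic given the seed.
* Eigenvector signs are fixed by making the largest-magnitude entry
  positive; eigenvalues are clipped below 1 to keep the
  $\lambda/(1-\lambda)$ scale finite.
* Zero-count cells: normalized rows stay all-zero and are flagged; QC
  defines their mitochondrial fraction as 0.
* Constant genes can never be selected as HVGs (z forced to $-\infty$);
  zero-variance genes leave PCA/Spearman with a log entry.
* Empty QC results warn rather than error; an empty lineage subset errors.

## Limitations

* Single-lineage pseudotime only — no branching inference; the rod/cone
  branch is handled by annotation, not by the trajectory model.
* No batch correction; analyses across strong batch effects need external
  integration first.
* The score is transcriptomic: it cannot see post-translational control of
  repair factors, and pathway activity at the protein level may differ.
* Exact signed-rank contrasts are powerless below six replicates
  ($p_{min} = 2/2^n$); reports carry the method used so this is visible.
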