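#' Gene sets for double-strand break repair pathway scoring
#'
#' A `gene_set` bundles an ordered list of gene symbols with the pathway it
#' describes and a per-gene functional role. The packaged sets cover the three
#' DSB repair pathways (NHEJ, MMEJ, HDR), stand-in cell-cycle phase sets, and a
#' stand-in retinal cell-type marker reference; users can load their own sets
#' from GMT or JSON with [read_gmt()] / [read_gene_sets_json()].
#'
#' @param name Short label for the set.
#' @param pathway One of `"NHEJ"`, `"MMEJ"`, `"HDR"`, `"CELL_CYCLE"`,
#'   `"MARKER"`.
#' @param species One of `"human"`, `"mouse"`, `"macaque"`, `"squirrel"`.
#' @param members A data frame with columns `symbol` and `role` (optionally
#'   `alias`), or a character vector of symbols (role then defaults to
#'   `"none"`). Protein aliases are metadata only and never used for
#'   expression-matrix lookup.
#'
#' @return A `gene_set` object: a list with elements `name`, `pathway`,
#'   `species` and `members` (a tibble with `symbol`, `role`, `alias`).
#' @export
#' @examples
#' gene_set("my_markers", "MARKER", "human", c("RHO", "GNAT1"))
gene_set <- function(name, pathway, species, members) {
  pathway <- match.arg(pathway, c("NHEJ", "MMEJ", "HDR", "CELL_CYCLE", "MARKER"))
  species <- match.arg(species, supported_species())
  if (is.character(members)) {
    members <- tibble(symbol = members, role = "none", alias = NA_character_)
  }
  members <- as_tibble(members)
  if (!"role" %in% names(members)) members$role <- "none"
  if (!"alias" %in% names(members)) members$alias <- NA_character_
  stopifnot(all(c("symbol", "role") %in% names(members)))
  if (nrow(members) == 0L) abort("a gene_set must have at least one member")
  if (anyDuplicated(members$symbol)) {
    abort(sprintf("duplicate symbols in gene set '%s'", name))
  }
  roles <- c("determinant", "protection", "resection", "SSA", "add-resection", "none")
  bad <- setdiff(unique(members$role), roles)
  if (length(bad)) abort(sprintf("unknown role(s): %s", paste(bad, collapse = ", ")))
  structure(
    list(name = name, pathway = pathway, species = species,
         members = members[c("symbol", "role", "alias")]),
    class = "gene_set"
  )
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s [%s, %s]: %d genes\n  %s\n",
              x$name, x$pathway, x$species, nrow(x$members),
              paste(x$members$symbol, collapse = ", ")))
  invisible(x)
}

#' @export
length.gene_set <- function(x) nrow(x$members)

supported_species <- function() c("human", "mouse", "macaque", "squirrel")

#' Symbols of a gene set
#'
#' @param set A [gene_set()].
#' @return Character vector of member symbols, in set order.
#' @export
set_symbols <- function(set) set$members$symbol

# ---- symbol mapping ---------------------------------------------------------

#' Cross-species gene symbol maps
#'
#' Maps curated human reference symbols into another species' nomenclature.
#' Mouse symbols follow the title-case convention (BRCA1 -> Brca1) with two
#' explicit overrides where the mouse gene name genuinely diverges (TP53BP1 ->
#' Trp53bp1, MRE11 -> Mre11a). Macaque and ground-squirrel expression tables
#' conventionally reuse human-style upper-case symbols, so those maps are the
#' identity. Overrides always take precedence over the default rule.
#'
#' @param from,to Source and target species.
#' @param overrides Named character vector of explicit symbol overrides,
#'   merged over the packaged defaults.
#' @return A `symbol_map` object.
#' @export
#' @examples
#' map_symbol("TP53BP1", symbol_map("human", "mouse"))
symbol_map <- function(from, to, overrides = NULL) {
  from <- match.arg(from, supported_species())
  to <- match.arg(to, supported_species())
  packaged <- .dsb_resource("dsb_gene_sets.json")$mouse_overrides
  base_over <- character(0)
  rule <- "identity"
  if (from == to || (from %in% c("human", "macaque", "squirrel") &&
                     to %in% c("human", "macaque", "squirrel"))) {
    rule <- "identity"
  } else if (to == "mouse") {
    rule <- "titlecase"
    base_over <- unlist(packaged)
  } else if (from == "mouse") {
    rule <- "uppercase"
    base_over <- setNames(names(unlist(packaged)), unlist(packaged))
  }
  if (!is.null(overrides)) base_over[names(overrides)] <- overrides
  structure(list(from = from, to = to, rule = rule, overrides = base_over),
            class = "symbol_map")
}

#' Map gene symbols between species nomenclatures
#'
#' @param symbol Character vector of non-empty gene symbols.
#' @param map A [symbol_map()].
#' @return Character vector of mapped symbols (total function: every non-empty
#'   input maps to a non-empty output).
#' @export
map_symbol <- function(symbol, map) {
  stopifnot(inherits(map, "symbol_map"), is.character(symbol), all(nzchar(symbol)))
  out <- switch(map$rule,
    identity  = symbol,
    titlecase = paste0(toupper(substr(symbol, 1, 1)), tolower(substring(symbol, 2))),
    uppercase = toupper(symbol)
  )
  hit <- symbol %in% names(map$overrides)
  out[hit] <- unname(map$overrides[symbol[hit]])
  out
}

map_gene_set <- function(set, to) {
  if (set$species == to) return(set)
  m <- symbol_map(set$species, to)
  set$members$symbol <- map_symbol(set$members$symbol, m)
  set$species <- to
  set
}

# ---- packaged resources -----------------------------------------------------

.dsb_resource <- function(file) {
  path <- system.file("extdata", file, package = "dsbscore", mustWork = TRUE)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

.sets_from_resource <- function(res, species) {
  sets <- res$sets
  out <- lapply(seq_len(nrow(sets)), function(i) {
    s <- gene_set(sets$name[i], sets$pathway[i], res$species_reference,
                  as_tibble(sets$members[[i]]))
    map_gene_set(s, species)
  })
  names(out) <- sets$name
  out
}

#' Load the curated DSB repair pathway gene sets
#'
#' Returns the three curated pathway sets: NHEJ (4 genes: XRCC5, XRCC6,
#' TP53BP1, WRN), MMEJ (5 genes: PARP1, RBBP8, MRE11, NBN, RAD50) and HDR
#' (8 genes: BRCA1, BRCA2, RAD51, PALB2, RPA1, RPA2, EXO1, BLM), rendered in
#' the requested species' symbol nomenclature. RPA1/RPA2 sit inside the HDR set
#' with role `SSA`, exactly as the curation tabulates them.
#'
#' @param species `"human"`, `"mouse"`, `"macaque"` or `"squirrel"`.
#' @return Named list of three [gene_set()] objects (`NHEJ`, `MMEJ`, `HDR`).
#' @export
#' @examples
#' sets <- load_dsb_sets("mouse")
#' set_symbols(sets$NHEJ)
load_dsb_sets <- function(species = "human") {
  if (!is.character(species) || length(species) != 1L ||
      !species %in% supported_species()) {
    abort(sprintf("unsupported species: %s", paste(species, collapse = ",")),
          class = "dsbscore_unsupported_species")
  }
  .sets_from_resource(.dsb_resource("dsb_gene_sets.json"), species)
}

#' Load the packaged cell-cycle phase gene sets
#'
#' The packaged G2/M (20 genes) and S (12 genes) lists are stand-ins built from
#' conventional cell-cycle markers; any user list can be swapped in via
#' [read_gmt()] or [read_gene_sets_json()].
#'
#' @inheritParams load_dsb_sets
#' @return Named list of [gene_set()] objects (`G2M`, `S`).
#' @export
cell_cycle_sets <- function(species = "human") {
  species <- match.arg(species, supported_species())
  .sets_from_resource(.dsb_resource("cell_cycle_sets_standin.json"), species)
}

#' Load the packaged retinal cell-type marker reference
#'
#' Stand-in canonical marker sets for major retinal cell classes, used by
#' [annotate_clusters_overlap()]; replaceable by any user reference.
#'
#' @inheritParams load_dsb_sets
#' @return Named list of MARKER [gene_set()] objects.
#' @export
retinal_marker_sets <- function(species = "human") {
  species <- match.arg(species, supported_species())
  .sets_from_resource(.dsb_resource("retinal_markers_standin.json"), species)
}

# ---- user-supplied formats --------------------------------------------------

#' Read gene sets from a GMT file
#'
#' GMT: one set per line, tab-separated `name`, `description`, then symbols.
#'
#' @param path Path to a GMT file.
#' @param pathway Pathway tag assigned to every set read (default `"MARKER"`).
#' @param species Species nomenclature of the symbols in the file.
#' @return Named list of [gene_set()] objects.
#' @export
read_gmt <- function(path, pathway = "MARKER", species = "human") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) abort("GMT line needs name, description and >=1 symbol")
    gene_set(f[1], pathway, species, f[-(1:2)])
  })
  names(out) <- vapply(out, `[[`, "", "name")
  out
}

#' Read gene sets from the packaged JSON dialect
#'
#' @param path Path to a JSON file in the same dialect as the packaged
#'   resources (`species_reference` plus a `sets` array of
#'   `{name, pathway, members}`).
#' @param species Target species nomenclature for the returned sets.
#' @return Named list of [gene_set()] objects.
#' @export
read_gene_sets_json <- function(path, species = NULL) {
  res <- jsonlite::read_json(path, simplifyVector = TRUE)
  species <- species %||% res$species_reference
  .sets_from_resource(res, species)
}
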