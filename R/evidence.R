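#' Load an evidence gene list, harmonized to human gene ids
#'
#' Reads a one-id-per-line evidence list and, for non-human species,
#' translates the ids to human gene ids through an ortholog map.
#' Many-to-many maps are resolved by crediting every mapped human gene;
#' unmapped ids are counted, not fatal.
#'
#' @param path Evidence list file (see [read_evidence_list()]).
#' @param species One of `"human"`, `"mouse"`, `"worm"`, `"fly"`.
#'   Non-human lists require `ortholog_map`.
#' @param ortholog_map Optional path to an ortholog map TSV, or a
#'   `data.frame` with columns `source_id`, `human_gene_id`.
#' @return A list with `genes` (character vector of human gene ids) and
#'   `report` (`n_listed`, `n_mapped`, `unmapped_ids`).
#' @export
load_evidence_list <- function(path, species = c("human", "mouse", "worm", "fly"),
                               ortholog_map = NULL) {
  species <- match.arg(species)
  ids <- unique(read_evidence_list(path))
  if (species == "human") {
    return(list(genes = ids,
                report = list(n_listed = length(ids), n_mapped = length(ids),
                              unmapped_ids = character(0))))
  }
  if (is.null(ortholog_map))
    config_error("%s evidence list requires an ortholog map", species)
  map <- if (is.character(ortholog_map)) read_ortholog_map(ortholog_map)
         else ortholog_map
  hit <- map[map$source_id %in% ids, , drop = FALSE]
  genes <- unique(hit$human_gene_id)
  unmapped <- setdiff(ids, map$source_id)
  list(genes = genes,
       report = list(n_listed = length(ids),
                     n_mapped = length(ids) - length(unmapped),
                     unmapped_ids = unmapped))
}

#' Assign linkage-interval evidence to genes
#'
#' A gene carries linkage evidence iff its body `[start, end]` overlaps
#' any interval by at least 1 bp. No flank is applied.
#'
#' @param gene_table Gene universe `data.frame`.
#' @param intervals Interval `data.frame` with `chrom`, `start`, `end`
#'   (1-based inclusive), e.g. from [read_linkage_bed()].
#' @return Character vector of member gene ids.
#' @export
assign_linkage <- function(gene_table, intervals) {
  if (!nrow(intervals) || !nrow(gene_table)) return(character(0))
  if (any(intervals$end < intervals$start))
    config_error("malformed interval: end < start")
  gr_genes <- genes_as_granges(gene_table)
  gr_ivl <- GenomicRanges::GRanges(
    seqnames = intervals$chrom,
    ranges = IRanges::IRanges(start = intervals$start, end = intervals$end))
  suppressWarnings(
    hits <- GenomicRanges::findOverlaps(gr_genes, gr_ivl, minoverlap = 1L))
  unique(gene_table$gene_id[S4Vectors::queryHits(hits)])
}

#' Build per-gene evidence profiles
#'
#' Combines the seven evidence membership sets into one profile per
#' universe gene, deriving the cross-species bonus flag (`Cross`) and
#' the initial-list flag. `Cross` is true iff the gene has evidence in
#' at least two distinct species among mouse (`MuAc` or `MuPref`),
#' human (`HuAlc` or `HuAddChip`), worm (`Ce`) and fly (`Dr`); linkage
#' membership (`HuLink`) never contributes to the species count.
#'
#' @param gene_table Gene universe `data.frame`.
#' @param source_sets Named list of human gene-id character vectors,
#'   keyed by exactly `MuAc`, `MuPref`, `HuAlc`, `HuAddChip`, `HuLink`,
#'   `Ce`, `Dr`.
#' @param initial_sources Sources whose union defines the initial
#'   candidate list to which scoring is restricted by default.
#' @return A `data.frame` with one row per universe gene: `gene_id`,
#'   `symbol`, seven logical indicator columns, `Cross`, and
#'   `in_initial_list`. The attribute `"dropped"` holds evidence ids
#'   absent from the universe (also raised as a warning).
#' @export
build_profiles <- function(gene_table, source_sets,
                           initial_sources = c("MuAc", "MuPref", "HuAlc")) {
  if (!setequal(names(source_sets), EVIDENCE_SOURCES))
    config_error("source_sets must be keyed by exactly: %s",
                 paste(EVIDENCE_SOURCES, collapse = ", "))
  stopifnot(all(initial_sources %in% EVIDENCE_SOURCES))
  universe <- gene_table$gene_id
  dropped <- sort(unique(unlist(lapply(source_sets, setdiff, y = universe),
                                use.names = FALSE)))
  if (length(dropped))
    warning(sprintf("%d evidence gene id(s) absent from universe; excluded",
                    length(dropped)))
  prof <- data.frame(gene_id = universe, symbol = gene_table$symbol,
                     stringsAsFactors = FALSE)
  for (s in EVIDENCE_SOURCES) prof[[s]] <- universe %in% source_sets[[s]]
  prof$Cross <- derive_cross(prof)
  prof$in_initial_list <- Reduce(`|`, lapply(initial_sources,
                                             function(s) prof[[s]]))
  attr(prof, "dropped") <- dropped
  prof
}

# Internal: cross-species bonus flag from indicator columns.
derive_cross <- function(prof) {
  species_hit <- cbind(
    mouse = prof$MuAc | prof$MuPref,
    human = prof$HuAlc | prof$HuAddChip,
    worm = prof$Ce,
    fly = prof$Dr
  )
  rowSums(species_hit) >= 2
}
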