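#' Read / write a gene universe table
#'
#' Plain TSV with columns `gene_id`, `symbol`, `chrom`, `start`, `end`.
#' Coordinates are 1-based inclusive.
#'
#' @param path File path.
#' @return `read_gene_table()`: a `data.frame`; `write_gene_table()`:
#'   `path`, invisibly.
#' @export
read_gene_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("gene_id", "symbol", "chrom", "start", "end")
  missing <- setdiff(required, names(df))
  if (length(missing))
    config_error("gene table %s lacks column(s): %s", path,
                 paste(missing, collapse = ", "))
  if (nrow(df) && any(df$end < df$start))
    config_error("gene table %s has end < start", path)
  df
}

#' @param gene_table Gene table `data.frame`.
#' @rdname read_gene_table
#' @export
write_gene_table <- function(gene_table, path) {
  utils::write.table(gene_table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write an evidence gene list
#'
#' One identifier per line; lines starting with `#` are comments.
#'
#' @param path File path.
#' @return `read_evidence_list()`: character vector of ids;
#'   `write_evidence_list()`: `path`, invisibly.
#' @export
read_evidence_list <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

#' @param ids Character vector of gene ids.
#' @param comment Optional comment line written at the top.
#' @rdname read_evidence_list
#' @export
write_evidence_list <- function(ids, path, comment = NULL) {
  out <- character(0)
  if (!is.null(comment)) out <- paste0("# ", comment)
  writeLines(c(out, ids), path)
  invisible(path)
}

#' Read / write an ortholog map
#'
#' TSV with columns `source_id` (non-human gene id) and `human_gene_id`.
#' Many-to-many rows are allowed.
#'
#' @param path File path.
#' @return `read_ortholog_map()`: a two-column `data.frame`;
#'   `write_ortholog_map()`: `path`, invisibly.
#' @export
read_ortholog_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("source_id", "human_gene_id") %in% names(df)))
    config_error("ortholog map %s needs columns source_id, human_gene_id",
                 path)
  df[c("source_id", "human_gene_id")]
}

#' @param map Ortholog map `data.frame`.
#' @rdname read_ortholog_map
#' @export
write_ortholog_map <- function(map, path) {
  utils::write.table(map, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write linkage intervals as BED
#'
#' On disk the intervals use BED semantics (0-based, half-open); in
#' memory they are 1-based inclusive, matching gene coordinates. The
#' conversion happens here and only here.
#'
#' @param path File path.
#' @return `read_linkage_bed()`: `data.frame` with `chrom`, `start`,
#'   `end` (1-based inclusive) and `label`; `write_linkage_bed()`:
#'   `path`, invisibly.
#' @export
read_linkage_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), label = character(0),
                      stringsAsFactors = FALSE))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  n <- lengths(parts)
  if (any(n < 3)) config_error("BED file %s has lines with < 3 fields", path)
  data.frame(
    chrom = vapply(parts, `[`, "", 1L),
    start = as.integer(vapply(parts, `[`, "", 2L)) + 1L,
    end = as.integer(vapply(parts, `[`, "", 3L)),
    label = vapply(parts, function(p) if (length(p) >= 4) p[4] else "", ""),
    stringsAsFactors = FALSE
  )
}

#' @param intervals Interval `data.frame` (1-based inclusive).
#' @rdname read_linkage_bed
#' @export
write_linkage_bed <- function(intervals, path) {
  if (nrow(intervals) && any(intervals$end < intervals$start))
    config_error("malformed interval: end < start")
  lab <- if ("label" %in% names(intervals)) intervals$label else
    paste0("ivl", seq_len(nrow(intervals)))
  lines <- sprintf("%s\t%d\t%d\t%s", intervals$chrom,
                   intervals$start - 1L, intervals$end, lab)
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a SNP marker table
#'
#' The native format is a TSV with columns `snp_id`, `chrom`, `pos`,
#' `p`, and optionally `call_rate`, `maf`, `hwe_p` and per-group
#' genotype counts (`case_AA`, `case_Aa`, `case_aa`, `ctrl_AA`,
#' `ctrl_Aa`, `ctrl_aa`). PLINK `.assoc`-style files (whitespace
#' separated, columns `CHR`, `SNP`, `BP`, `P`) are also accepted and
#' normalized to the native column names.
#'
#' @param path File path.
#' @return `read_snp_table()`: a `data.frame`; `write_snp_table()`:
#'   `path`, invisibly.
#' @export
read_snp_table <- function(path) {
  header <- strsplit(trimws(readLines(path, n = 1L)), "[ \t]+")[[1]]
  if (all(c("CHR", "SNP", "BP", "P") %in% header)) {
    df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
    df <- data.frame(snp_id = as.character(df$SNP), chrom = as.character(df$CHR),
                     pos = as.integer(df$BP), p = as.numeric(df$P),
                     stringsAsFactors = FALSE)
    return(df)
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("snp_id", "chrom", "pos", "p")
  missing <- setdiff(required, names(df))
  if (length(missing))
    config_error("SNP table %s lacks column(s): %s", path,
                 paste(missing, collapse = ", "))
  df$chrom <- as.character(df$chrom)
  df
}

#' @param snps SNP table `data.frame`.
#' @rdname read_snp_table
#' @export
write_snp_table <- function(snps, path) {
  utils::write.table(snps, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write gene set collections in GMT format
#'
#' Standard GMT: one set per line — name, description, then member gene
#' ids, tab separated. Reading goes through [fgsea::gmtPathways()].
#'
#' @param path File path.
#' @return `read_gmt()`: a named list of character vectors;
#'   `write_gmt()`: `path`, invisibly.
#' @export
read_gmt <- function(path) {
  sets <- fgsea::gmtPathways(path)
  lapply(sets, unique)
}

#' @param sets Named list of character vectors.
#' @param descriptions Optional character vector of per-set
#'   descriptions (defaults to the set name).
#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    config_error("all gene sets must be named")
  if (is.null(descriptions)) descriptions <- names(sets)
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
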