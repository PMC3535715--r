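#' QC configuration for GWAS markers
#'
#' Defaults follow common GWAS practice: markers are dropped when their
#' missingness (1 - call rate) exceeds 0.05, their minor allele
#' frequency is below 0.01, or their Hardy-Weinberg exact-test p-value
#' (computed in controls by default) falls below `hwe_alpha`.
#'
#' @param max_fail_rate Maximum per-marker missingness.
#' @param min_maf Minimum minor allele frequency.
#' @param hwe_alpha HWE exact-test significance cut-off.
#' @param hwe_group Group in which HWE is tested: `"controls"` or
#'   `"all"` (cases + controls pooled).
#' @return A `crossrank_qc_config` list.
#' @export
qc_config <- function(max_fail_rate = 0.05, min_maf = 0.01,
                      hwe_alpha = 1e-6, hwe_group = c("controls", "all")) {
  hwe_group <- match.arg(hwe_group)
  stopifnot(max_fail_rate >= 0, max_fail_rate <= 1,
            min_maf >= 0, min_maf <= 1, hwe_alpha >= 0, hwe_alpha <= 1)
  structure(list(max_fail_rate = max_fail_rate, min_maf = min_maf,
                 hwe_alpha = hwe_alpha, hwe_group = hwe_group),
            class = "crossrank_qc_config")
}

#' Hardy-Weinberg exact test from genotype counts
#'
#' Exact two-sided test: conditioning on the observed allele counts,
#' sums the probabilities of all heterozygote configurations no more
#' probable than the observed one. Monomorphic markers return 1 by
#' convention.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts.
#' @return Exact p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n == 0) config_error("all-zero genotype counts: HWE undefined")
  n_a <- 2 * n_aa + n_Aa           # rare-side allele count (either side works)
  n_A <- 2 * n_AA + n_Aa
  rare <- min(n_a, n_A)
  if (rare == 0) return(1)         # monomorphic
  # possible heterozygote counts share the parity of the rare allele count
  het <- seq(rare %% 2, rare, by = 2)
  # log P(nAa = h | n, rare) = log multinomial + h*log 2 - log C(2n, rare)
  logp <- lfactorial(n) - lfactorial((rare - het) / 2) - lfactorial(het) -
    lfactorial(n - (rare + het) / 2) + het * log(2) -
    (lfactorial(2 * n) - lfactorial(rare) - lfactorial(2 * n - rare))
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  obs <- which(het == n_Aa)
  if (!length(obs)) config_error("genotype counts inconsistent with alleles")
  min(1, sum(prob[prob <= prob[obs] * (1 + 1e-12)]))
}

#' Per-marker statistics from genotype counts
#'
#' Computes call rate, pooled minor allele frequency, and the HWE
#' exact-test p-value in the configured group.
#'
#' @param case_counts,control_counts Numeric length-3 vectors
#'   `(AA, Aa, aa)`; either may be `NULL`.
#' @param n_cases,n_controls Genotyped-sample denominators for the call
#'   rate; if `NULL` the call rate is `NA`.
#' @param hwe_group `"controls"` (default) or `"all"`.
#' @return A list `call_rate`, `maf`, `hwe_p`, plus per-group
#'   `maf_cases` / `maf_controls` for audit.
#' @export
snp_stats <- function(case_counts = NULL, control_counts = NULL,
                      n_cases = NULL, n_controls = NULL,
                      hwe_group = c("controls", "all")) {
  hwe_group <- match.arg(hwe_group)
  if (is.null(case_counts) && is.null(control_counts))
    config_error("at least one group's genotype counts are required")
  as3 <- function(x) if (is.null(x)) c(0, 0, 0) else {
    stopifnot(length(x) == 3, all(x >= 0)); as.numeric(x)
  }
  cc <- as3(case_counts); ct <- as3(control_counts)
  pooled <- cc + ct
  if (sum(pooled) == 0)
    config_error("all-zero genotype counts: statistics undefined")
  freq_a <- function(g) if (sum(g) == 0) NA_real_ else
    (g[2] + 2 * g[3]) / (2 * sum(g))
  maf_of <- function(g) { f <- freq_a(g); if (is.na(f)) NA_real_ else min(f, 1 - f) }
  call_rate <- if (is.null(n_cases) && is.null(n_controls)) NA_real_ else
    sum(pooled) / sum(c(n_cases, n_controls))
  hwe_counts <- if (hwe_group == "controls" && sum(ct) > 0) ct else pooled
  list(call_rate = call_rate,
       maf = maf_of(pooled),
       hwe_p = hwe_exact_test(hwe_counts[1], hwe_counts[2], hwe_counts[3]),
       maf_cases = maf_of(cc),
       maf_controls = maf_of(ct))
}

#' QC-filter a SNP table
#'
#' Keeps markers passing all three rules (missingness, MAF, HWE) and
#' reports exclusions attributed to the first failing rule in the
#' order: call rate, MAF, HWE. Markers lacking a statistic (`NA` or
#' absent column) pass the corresponding rule.
#'
#' @param snps SNP `data.frame` with `p` and any of `call_rate`,
#'   `maf`, `hwe_p`. If genotype-count columns (`ctrl_AA` etc.) are
#'   present, missing statistics are computed from them.
#' @param cfg A [qc_config()].
#' @return List with `snps` (passing rows, input order preserved) and
#'   `report` (per-reason exclusion counts).
#' @export
qc_filter <- function(snps, cfg = qc_config()) {
  stopifnot(inherits(cfg, "crossrank_qc_config"))
  n <- nrow(snps)
  geno_cols <- c("case_AA", "case_Aa", "case_aa", "ctrl_AA", "ctrl_Aa", "ctrl_aa")
  have_geno <- all(geno_cols %in% names(snps))
  get_stat <- function(col, compute) {
    if (col %in% names(snps)) return(snps[[col]])
    if (have_geno) return(compute())
    rep(NA_real_, n)
  }
  maf <- get_stat("maf", function() vapply(seq_len(n), function(i) {
    snp_stats(unlist(snps[i, geno_cols[1:3]]), unlist(snps[i, geno_cols[4:6]]))$maf
  }, 0))
  hwe_p <- get_stat("hwe_p", function() vapply(seq_len(n), function(i) {
    snp_stats(unlist(snps[i, geno_cols[1:3]]), unlist(snps[i, geno_cols[4:6]]),
              hwe_group = cfg$hwe_group)$hwe_p
  }, 0))
  call_rate <- if ("call_rate" %in% names(snps)) snps$call_rate else
    rep(NA_real_, n)

  # small additive tolerance so markers exactly at a threshold pass
  eps <- 1e-12
  pass_or_na <- function(x, ok) is.na(x) | ok
  ok_call <- pass_or_na(call_rate, (1 - call_rate) <= cfg$max_fail_rate + eps)
  ok_maf <- pass_or_na(maf, maf >= cfg$min_maf - eps)
  ok_hwe <- pass_or_na(hwe_p, hwe_p >= cfg$hwe_alpha * (1 - 1e-9))

  reason <- rep(NA_character_, n)
  reason[!ok_hwe] <- "hwe"
  reason[!ok_maf] <- "maf"          # overrides hwe: earlier rule wins
  reason[!ok_call] <- "call_rate"
  keep <- is.na(reason)
  list(
    snps = snps[keep, , drop = FALSE],
    report = list(
      n_input = n, n_pass = sum(keep),
      excluded_call_rate = sum(reason == "call_rate", na.rm = TRUE),
      excluded_maf = sum(reason == "maf", na.rm = TRUE),
      excluded_hwe = sum(reason == "hwe", na.rm = TRUE)
    )
  )
}

#' Allelic association test on a 2x2 allele-count table
#'
#' One-degree-of-freedom chi-square without continuity correction,
#' comparing allele counts between cases and controls. Tables with a
#' zero margin return p = 1.
#'
#' @param case_alleles,control_alleles Numeric length-2 vectors
#'   `(A, a)` of allele counts.
#' @return Chi-square p-value in (0, 1].
#' @export
allelic_test <- function(case_alleles, control_alleles) {
  stopifnot(length(case_alleles) == 2, length(control_alleles) == 2)
  tab <- rbind(as.numeric(case_alleles), as.numeric(control_alleles))
  if (any(tab < 0)) config_error("negative allele counts")
  if (sum(tab) <= 0) config_error("empty allele-count table")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(1)
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  chi2 <- sum((tab - e)^2 / e)
  stats::pchisq(chi2, df = 1, lower.tail = FALSE)
}

#' Map SNPs to genes with a flanking window
#'
#' A SNP belongs to a gene iff its position lies within
#' `[start - flank_bp, end + flank_bp]` (both ends inclusive). A SNP
#' may map to several genes; unmapped SNPs are retained with an empty
#' mapping.
#'
#' @param snps SNP `data.frame` (`snp_id`, `chrom`, `pos`, ...).
#' @param gene_table Gene universe `data.frame`.
#' @param flank_bp Flank in bp on each side (default 10000).
#' @return A `crossrank_mapping` list: `map` (`data.frame` with one row
#'   per SNP-gene pair), `by_gene` (named list gene id -> SNP ids),
#'   `n_snps`, `mapped_fraction`, `flank_bp`.
#' @export
map_snps_to_genes <- function(snps, gene_table, flank_bp = 10000) {
  stopifnot(flank_bp >= 0)
  if (!nrow(snps) || !nrow(gene_table)) {
    return(structure(list(
      map = data.frame(snp_id = character(0), gene_id = character(0),
                       stringsAsFactors = FALSE),
      by_gene = list(), n_snps = nrow(snps), mapped_fraction = 0,
      flank_bp = flank_bp), class = "crossrank_mapping"))
  }
  gr_snps <- GenomicRanges::GRanges(
    seqnames = snps$chrom,
    ranges = IRanges::IRanges(start = snps$pos, width = 1L))
  gr_genes <- genes_as_granges(gene_table, flank_bp = flank_bp)
  suppressWarnings(
    hits <- GenomicRanges::findOverlaps(gr_snps, gr_genes))
  map <- data.frame(
    snp_id = snps$snp_id[S4Vectors::queryHits(hits)],
    gene_id = gene_table$gene_id[S4Vectors::subjectHits(hits)],
    stringsAsFactors = FALSE)
  structure(list(
    map = map,
    by_gene = split(map$snp_id, map$gene_id),
    n_snps = nrow(snps),
    mapped_fraction = length(unique(map$snp_id)) / nrow(snps),
    flank_bp = flank_bp), class = "crossrank_mapping")
}

#' Distinct SNP ids mapped to a gene subset
#'
#' @param mapping A `crossrank_mapping` from [map_snps_to_genes()].
#' @param gene_ids Character vector of gene ids.
#' @return Character vector of distinct SNP ids (each counted once even
#'   if mapped to several subset genes).
#' @export
snps_for_genes <- function(mapping, gene_ids) {
  stopifnot(inherits(mapping, "crossrank_mapping"))
  unique(mapping$map$snp_id[mapping$map$gene_id %in% gene_ids])
}
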