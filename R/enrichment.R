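#' Hypergeometric upper-tail probability
#'
#' \eqn{P(X \ge k)} for \eqn{X \sim} Hypergeometric(`N` genes, `K` in
#' the set, `n` drawn), i.e. the probability of an overlap at least as
#' large as observed between a query list of size `n` and a gene set
#' of size `K` on a background of `N` genes. Evaluated via
#' `stats::phyper()` on the upper tail, which works in log space
#' internally and is stable for genome-scale `N`.
#'
#' @param k Observed overlap.
#' @param n Query size.
#' @param K Set size within the background.
#' @param N Background size.
#' @return Upper-tail probability in (0, 1].
#' @export
#' @examples
#' hypergeom_upper(4, 4, 5, 10)  # 5/210
hypergeom_upper <- function(k, n, K, N) {
  stopifnot(length(k) == 1, length(n) == 1, length(K) == 1, length(N) == 1)
  if (k < 0 || n < 0 || K < 0 || N < 0 || k > min(n, K) || n > N || K > N)
    config_error("inconsistent hypergeometric counts (k=%s n=%s K=%s N=%s)",
                 k, n, K, N)
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Over-representation analysis against a GMT collection
#'
#' Flat hypergeometric enrichment of a query gene list against each set
#' in a collection, with Benjamini-Hochberg adjustment across the
#' collection. Query genes outside the background are dropped (count
#' recorded); set members are intersected with the background.
#'
#' @param query Character vector of gene ids.
#' @param collection Named list of gene sets (e.g. from [read_gmt()]).
#' @param background Character vector of background gene ids, or a
#'   single integer taken as an explicit background size `N` (in which
#'   case sets and query are used as given).
#' @param min_overlap Minimum overlap `k` for a set to be reported.
#' @return A `data.frame` (`set`, `k`, `n`, `K`, `N`, `p`, `p_BH`)
#'   sorted ascending by `p`; the attribute `"n_query_dropped"` counts
#'   query genes outside the background.
#' @export
enrich <- function(query, collection, background, min_overlap = 1) {
  if (!length(collection)) config_error("empty gene set collection")
  query <- unique(query)
  if (is.numeric(background) && length(background) == 1) {
    N <- as.integer(background)
    dropped <- 0L
    sets <- lapply(collection, unique)
  } else {
    background <- unique(background)
    N <- length(background)
    dropped <- sum(!query %in% background)
    query <- intersect(query, background)
    sets <- lapply(collection, intersect, y = background)
  }
  n <- length(query)
  res <- data.frame(
    set = names(collection),
    k = vapply(sets, function(s) length(intersect(query, s)), 0L),
    n = n,
    K = vapply(sets, length, 0L),
    N = N,
    stringsAsFactors = FALSE)
  if (any(res$K > N))
    config_error("a gene set is larger than the background")
  res$p <- vapply(seq_len(nrow(res)), function(i)
    hypergeom_upper(res$k[i], res$n[i], res$K[i], res$N[i]), 0)
  res$p_BH <- stats::p.adjust(res$p, method = "BH")
  res <- res[res$k >= min_overlap, , drop = FALSE]
  res <- res[order(res$p, res$set), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_query_dropped") <- dropped
  res
}

#' Min-p gene ranking from mapped SNP p-values
#'
#' Assigns each gene the smallest association p-value among its mapped
#' SNPs and returns the `k` most significant genes. Ties on min p are
#' broken by SNP count (more SNPs first) then symbol. Genes with no
#' mapped SNPs are excluded. This is the gene-length-biased baseline
#' that evidence-based ranking is compared against.
#'
#' @param mapping A `crossrank_mapping` from [map_snps_to_genes()].
#' @param snps SNP `data.frame` with `snp_id`, `p`.
#' @param k Number of genes to return.
#' @param gene_table Optional gene table supplying symbols for the tie
#'   break (gene ids are used otherwise).
#' @return A `data.frame` (`gene_id`, `symbol`, `min_p`, `n_snps`),
#'   ascending by `min_p`, at most `k` rows.
#' @export
min_p_gene_ranking <- function(mapping, snps, k, gene_table = NULL) {
  stopifnot(inherits(mapping, "crossrank_mapping"))
  if (!nrow(mapping$map)) config_error("empty SNP-gene mapping")
  if (k == 0)
    return(data.frame(gene_id = character(0), symbol = character(0),
                      min_p = numeric(0), n_snps = integer(0)))
  p <- snps$p[match(mapping$map$snp_id, snps$snp_id)]
  by_gene <- split(p, mapping$map$gene_id)
  res <- data.frame(
    gene_id = names(by_gene),
    min_p = vapply(by_gene, min, 0),
    n_snps = lengths(by_gene),
    stringsAsFactors = FALSE)
  res$symbol <- if (!is.null(gene_table))
    gene_table$symbol[match(res$gene_id, gene_table$gene_id)] else res$gene_id
  if (k > nrow(res)) {
    warning(sprintf("requested %d genes but only %d have mapped SNPs", k,
                    nrow(res)))
    k <- nrow(res)
  }
  res <- res[order(res$min_p, -res$n_snps, res$symbol), , drop = FALSE]
  res <- res[seq_len(k), c("gene_id", "symbol", "min_p", "n_snps"),
             drop = FALSE]
  rownames(res) <- NULL
  res
}
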