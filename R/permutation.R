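#' Configuration for length-matched permutation evaluation
#'
#' @param B Number of permutations (screening default 100; a refined
#'   run conventionally uses 1000).
#' @param length_tol_bp Half-width of the gene-length matching window
#'   around the mean length of the observed gene set (default 50 kb).
#' @param thresholds Score cutoffs evaluated as `score >= cutoff`.
#' @param eq_thresholds Score cutoffs evaluated as `score == cutoff`.
#' @param q_bins Strictly decreasing q-value thresholds (see
#'   [bin_q()]).
#' @param seed Integer seed for the permutation stream.
#' @param tie_rule `"strict_greater"` counts a permutation as
#'   significant only when its bin proportion strictly exceeds the
#'   observed one (the classical estimator, which can return 0);
#'   `"greater_equal"` also counts ties. The add-one estimator
#'   `(x+1)/(B+1)` is reported alongside either way.
#' @param widen_on_small_pool If the matching pool holds fewer genes
#'   than needed, double the tolerance until it suffices (each widening
#'   recorded); if `FALSE`, error instead.
#' @return A `crossrank_perm_config` list.
#' @export
perm_config <- function(B = 100, length_tol_bp = 50000,
                        thresholds = c(0.5, 1, 1.5, 2),
                        eq_thresholds = 2.5,
                        q_bins = seq(0.9, 0.4, by = -0.1),
                        seed = 1L,
                        tie_rule = c("strict_greater", "greater_equal"),
                        widen_on_small_pool = TRUE) {
  tie_rule <- match.arg(tie_rule)
  stopifnot(B >= 1, length_tol_bp >= 0)
  structure(list(B = as.integer(B), length_tol_bp = length_tol_bp,
                 thresholds = thresholds, eq_thresholds = eq_thresholds,
                 q_bins = q_bins, seed = as.integer(seed),
                 tie_rule = tie_rule,
                 widen_on_small_pool = isTRUE(widen_on_small_pool)),
            class = "crossrank_perm_config")
}

#' Mean gene length of a gene set
#'
#' Arithmetic mean of `end - start + 1` over the listed genes.
#'
#' @param gene_ids Character vector of gene ids (non-empty).
#' @param gene_table Gene universe `data.frame`.
#' @return Mean length in bp.
#' @export
mean_length <- function(gene_ids, gene_table) {
  if (!length(gene_ids)) config_error("empty gene list")
  idx <- match(gene_ids, gene_table$gene_id)
  if (anyNA(idx)) config_error("gene id(s) absent from the gene table")
  mean(gene_lengths(gene_table)[idx])
}

#' Sample a gene-length-matched random gene set
#'
#' Draws `n` distinct genes uniformly without replacement from the
#' pool of universe genes whose length lies within `length_tol_bp` of
#' `target_len`. If the pool is too small and widening is enabled, the
#' tolerance doubles until the pool suffices.
#'
#' @param gene_table Gene universe `data.frame`.
#' @param n Sample size.
#' @param target_len Target mean length in bp.
#' @param cfg A [perm_config()].
#' @return Character vector of `n` gene ids; the attribute
#'   `"widenings"` records how many times the tolerance was doubled.
#' @export
sample_matched <- function(gene_table, n, target_len, cfg = perm_config()) {
  if (!nrow(gene_table)) config_error("empty gene universe")
  stopifnot(n >= 1)
  lens <- gene_lengths(gene_table)
  tol <- cfg$length_tol_bp
  widenings <- 0L
  repeat {
    pool <- which(abs(lens - target_len) <= tol)
    if (length(pool) >= n) break
    if (!cfg$widen_on_small_pool)
      config_error("matching pool has %d gene(s), need %d (tol %.0f bp)",
                   length(pool), n, tol)
    tol <- if (tol > 0) tol * 2 else max(1, target_len)
    widenings <- widenings + 1L
  }
  ids <- gene_table$gene_id[sample(pool, n)]
  attr(ids, "widenings") <- widenings
  ids
}

#' Length-matched permutation evaluation of a ranked gene list
#'
#' For each score cutoff, the observed gene set is the ranked genes at
#' or above (or exactly at) the cutoff; its mapped SNPs get subset
#' q-values and cumulative q-bin proportions. Each of `B` permutations
#' draws a random gene set of the same size, matched on mean gene
#' length, and the empirical p-value per q-bin is the fraction of
#' permutations whose bin proportion exceeds the observed one
#' (per `cfg$tie_rule`). Bins with zero observed SNPs are reported as
#' `NA`.
#'
#' @param scores Ranked gene `data.frame` from [rank_genes()].
#' @param mapping A `crossrank_mapping` from [map_snps_to_genes()].
#' @param snps SNP `data.frame` with `snp_id`, `p`.
#' @param gene_table Gene universe `data.frame` (matching pool).
#' @param cfg A [perm_config()].
#' @param ... Passed to [storey_q()] (e.g. `pi0_method`).
#' @return A `crossrank_perm_report`: `table` (one row per cutoff x
#'   q-bin with observed count/proportion, permutation mean proportion,
#'   `p_emp`, `p_add_one`), `cutoffs` (per-cutoff `n_genes`, `n_snps`,
#'   observed `min_q`), and the config used.
#' @export
permutation_pvalues <- function(scores, mapping, snps, gene_table,
                                cfg = perm_config(), ...) {
  stopifnot(inherits(cfg, "crossrank_perm_config"))
  cuts <- rbind(
    if (length(cfg$thresholds))
      data.frame(cutoff = cfg$thresholds, mode = "ge"),
    if (length(cfg$eq_thresholds))
      data.frame(cutoff = cfg$eq_thresholds, mode = "eq"))
  rows <- list(); cut_rows <- list()
  with_seed(cfg$seed, {
    for (i in seq_len(nrow(cuts))) {
      s <- cuts$cutoff[i]; mode <- cuts$mode[i]
      sel <- select_top(scores, s, mode)$gene_id
      label <- paste0(ifelse(mode == "ge", ">=", "="), s)
      if (!length(sel)) {
        cut_rows[[label]] <- data.frame(cutoff = label, n_genes = 0L,
                                        n_snps = 0L, min_q = NA_real_)
        next
      }
      obs_q <- suppressWarnings(subset_q(snps, sel, mapping, ...))
      obs_bins <- bin_q(obs_q, cfg$q_bins)
      target_len <- mean_length(sel, gene_table)
      exceed <- integer(length(cfg$q_bins))
      perm_prop_sum <- numeric(length(cfg$q_bins))
      for (b in seq_len(cfg$B)) {
        rand <- sample_matched(gene_table, length(sel), target_len, cfg)
        rq <- suppressWarnings(subset_q(snps, rand, mapping, ...))
        rprop <- bin_q(rq, cfg$q_bins)$table$proportion
        rprop[is.na(rprop)] <- 0
        oprop <- obs_bins$table$proportion
        hit <- if (cfg$tie_rule == "strict_greater") rprop > oprop
               else rprop >= oprop
        exceed <- exceed + hit
        perm_prop_sum <- perm_prop_sum + rprop
      }
      populated <- obs_bins$table$count > 0
      rows[[label]] <- data.frame(
        cutoff = label,
        q_threshold = cfg$q_bins,
        n_snps = obs_q$n,
        observed_count = obs_bins$table$count,
        observed_prop = obs_bins$table$proportion,
        perm_mean_prop = perm_prop_sum / cfg$B,
        p_emp = ifelse(populated, exceed / cfg$B, NA_real_),
        p_add_one = ifelse(populated, (exceed + 1) / (cfg$B + 1), NA_real_))
      cut_rows[[label]] <- data.frame(cutoff = label,
                                      n_genes = length(sel),
                                      n_snps = obs_q$n,
                                      min_q = obs_bins$min_q)
    }
  })
  empty_tab <- data.frame(cutoff = character(0), q_threshold = numeric(0),
                          n_snps = integer(0), observed_count = integer(0),
                          observed_prop = numeric(0),
                          perm_mean_prop = numeric(0),
                          p_emp = numeric(0), p_add_one = numeric(0))
  structure(list(
    table = if (length(rows))
      do.call(rbind, c(rows, list(make.row.names = FALSE))) else empty_tab,
    cutoffs = if (length(cut_rows))
      do.call(rbind, c(cut_rows, list(make.row.names = FALSE))) else
      data.frame(cutoff = character(0), n_genes = integer(0),
                 n_snps = integer(0), min_q = numeric(0)),
    cfg = cfg), class = "crossrank_perm_report")
}

#' Select the best-performing weighting matrix
#'
#' Orders matrices by the smallest observed min q over all cutoffs;
#' ties are broken by (1) more SNPs with q < 0.5 and (2) smaller
#' empirical p at the most stringent populated q-bin. All criterion
#' values are returned so the choice is auditable.
#'
#' @param reports Named list of `crossrank_perm_report`s, one per
#'   weighting matrix.
#' @return List with `best` (matrix name) and `ranking` (criterion
#'   table ordered best first).
#' @export
select_best_matrix <- function(reports) {
  if (!length(reports)) config_error("no permutation reports supplied")
  if (is.null(names(reports)) || any(!nzchar(names(reports))))
    config_error("reports must be named by weighting matrix")
  crit <- lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    tab <- r$table
    min_q <- suppressWarnings(min(r$cutoffs$min_q, na.rm = TRUE))
    if (!is.finite(min_q)) min_q <- NA_real_
    q05 <- tab[abs(tab$q_threshold - 0.5) < 1e-9, , drop = FALSE]
    n_q_lt_05 <- if (nrow(q05)) max(q05$observed_count) else 0L
    pop <- tab[tab$observed_count > 0 & !is.na(tab$p_emp), , drop = FALSE]
    p_stringent <- if (nrow(pop)) {
      pop <- pop[order(pop$q_threshold), , drop = FALSE]
      min(pop$p_emp[pop$q_threshold == pop$q_threshold[1]])
    } else NA_real_
    data.frame(wsm = nm, min_q = min_q, n_q_lt_05 = n_q_lt_05,
               p_stringent = p_stringent, stringsAsFactors = FALSE)
  })
  ranking <- do.call(rbind, crit)
  ord <- order(ranking$min_q, -ranking$n_q_lt_05, ranking$p_stringent,
               ranking$wsm, na.last = TRUE)
  ranking <- ranking[ord, , drop = FALSE]
  rownames(ranking) <- NULL
  list(best = ranking$wsm[1], ranking = ranking)
}
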