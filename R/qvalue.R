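#' Benjamini-Hochberg adjusted p-values
#'
#' Thin validated wrapper around `stats::p.adjust(method = "BH")`:
#' step-up adjusted values, clipped at 1, monotone in rank.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return Adjusted p-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) config_error("empty p-value vector")
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    config_error("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Storey q-values
#'
#' Computes q-values \eqn{q_i = \min_{j: p_j \ge p_i}
#' \hat\pi_0 m p_j / rank_j}, where \eqn{\hat\pi_0} estimates the null
#' proportion. Tied p-values receive the same q (max-rank convention),
#' so q is monotone non-decreasing in p.
#'
#' `pi0_method`:
#' \describe{
#'   \item{`"smoother"`}{\eqn{\hat\pi_0(\lambda)} over a grid, smoothed
#'     by a cubic smoothing spline and read off at the largest
#'     \eqn{\lambda} (Storey's smoother). If any grid point has no
#'     p-values above it, falls back to `fixed` at \eqn{\lambda = 0.5}
#'     with a warning.}
#'   \item{`"fixed"`}{\eqn{\hat\pi_0 = \#\{p > \lambda\} /
#'     (m (1-\lambda))} at `lambda_fixed`.}
#'   \item{`"bh"`}{\eqn{\hat\pi_0 = 1}; the q-values then equal
#'     [bh_adjust()] exactly.}
#' }
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @param lambda_grid Grid for the smoother (default 0.05..0.95 by
#'   0.05).
#' @param pi0_method Null-proportion estimator (see Details).
#' @param lambda_fixed Lambda for `pi0_method = "fixed"`.
#' @return A `crossrank_qvector`: list with `p`, `q` (aligned), `pi0`,
#'   `method`, `n`.
#' @export
storey_q <- function(p, lambda_grid = seq(0.05, 0.95, by = 0.05),
                     pi0_method = c("smoother", "fixed", "bh"),
                     lambda_fixed = 0.5) {
  pi0_method <- match.arg(pi0_method)
  if (!length(p)) config_error("empty p-value vector")
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    config_error("p-values must lie in (0, 1]")
  m <- length(p)
  pi0_fixed <- function(lam) {
    est <- sum(p > lam) / (m * (1 - lam))
    min(1, max(est, 1 / m))
  }
  pi0 <- switch(pi0_method,
    bh = 1,
    fixed = pi0_fixed(lambda_fixed),
    smoother = {
      counts <- vapply(lambda_grid, function(l) sum(p > l), 0L)
      if (m < 100 || any(counts == 0)) {
        warning("too few p-values for the pi0 smoother; using fixed lambda = 0.5")
        pi0_fixed(0.5)
      } else {
        pi0_l <- counts / (m * (1 - lambda_grid))
        fit <- stats::smooth.spline(lambda_grid, pi0_l, df = 3)
        est <- stats::predict(fit, x = max(lambda_grid))$y
        min(1, max(est, 1 / m))
      }
    })
  o <- order(p)
  q_sorted <- pi0 * m * p[o] / seq_len(m)
  q_sorted <- rev(cummin(rev(pmin(q_sorted, 1))))
  q <- numeric(m)
  q[o] <- q_sorted
  structure(list(p = p, q = q, pi0 = pi0, method = pi0_method, n = m),
            class = "crossrank_qvector")
}

#' @export
print.crossrank_qvector <- function(x, ...) {
  cat(sprintf("q-vector: %d tests, pi0 = %.3f (%s), min q = %.4g\n",
              x$n, x$pi0, x$method, if (x$n) min(x$q) else NA))
  invisible(x)
}

#' Subset-restricted q-values
#'
#' Recomputes q-values from scratch over only the SNPs mapped to a
#' gene subset (never sliced from a global q-vector: the null
#' proportion and ranks are re-estimated within the subset). A SNP
#' mapping to several subset genes is counted once.
#'
#' @param snps SNP `data.frame` with `snp_id` and `p`.
#' @param gene_subset Character vector of gene ids.
#' @param mapping A `crossrank_mapping` from [map_snps_to_genes()].
#' @param ... Passed to [storey_q()].
#' @return A `crossrank_qvector` with an extra `snp_id` element; empty
#'   subsets yield a zero-length q-vector with a warning.
#' @export
subset_q <- function(snps, gene_subset, mapping, ...) {
  ids <- snps_for_genes(mapping, gene_subset)
  if (!length(ids)) {
    warning("no SNPs mapped to the gene subset; empty q-vector")
    return(structure(list(p = numeric(0), q = numeric(0), pi0 = NA_real_,
                          method = NA_character_, n = 0L,
                          snp_id = character(0)),
                     class = "crossrank_qvector"))
  }
  p <- snps$p[match(ids, snps$snp_id)]
  if (anyNA(p)) config_error("mapped SNP ids missing from the SNP table")
  qv <- storey_q(p, ...)
  qv$snp_id <- ids
  qv
}

#' Cumulative q-value binning
#'
#' Counts q-values strictly below each threshold (thresholds must be
#' strictly decreasing), mirroring the q-bin summaries used to compare
#' ranked gene subsets.
#'
#' @param qv A `crossrank_qvector`.
#' @param thresholds Strictly decreasing thresholds (default 0.9..0.4).
#' @return A `crossrank_qbin_table`: `table` (`threshold`, `count`,
#'   `proportion`), `min_q` (`NA` when empty), `n`.
#' @export
bin_q <- function(qv, thresholds = seq(0.9, 0.4, by = -0.1)) {
  stopifnot(inherits(qv, "crossrank_qvector"))
  if (length(thresholds) > 1 && any(diff(thresholds) >= 0))
    config_error("thresholds must be strictly decreasing")
  counts <- vapply(thresholds, function(t) sum(qv$q < t), 0L)
  structure(list(
    table = data.frame(
      threshold = thresholds, count = counts,
      proportion = if (qv$n) counts / qv$n else rep(NA_real_, length(counts))),
    min_q = if (qv$n) min(qv$q) else NA_real_,
    n = qv$n), class = "crossrank_qbin_table")
}
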