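#' Weighting matrices for evidence scoring
#'
#' The evidence score of a gene is
#' \deqn{S = w_1 MuAc + w_2 MuPref + w_3 HuAlc + w_4 HuAddChip +
#'           w_5 HuLink + w_6 Ce + w_7 Dr + w_8 Cross}
#' with the indicators coded 0/1. `weighting_matrix()` builds a custom
#' matrix; `wsm_presets()` returns the ten preset matrices
#' (`WSM1`..`WSM10`, weights in \{0.5, 1\}) explored in cross-species
#' candidate prioritization, and `wsm_preset(name)` one of them.
#'
#' @param name Matrix name.
#' @param weights Numeric vector of 8 non-negative weights, in term
#'   order `MuAc`, `MuPref`, `HuAlc`, `HuAddChip`, `HuLink`, `Ce`,
#'   `Dr`, `Cross`.
#' @return A `crossrank_wsm` object (named numeric weight vector with a
#'   `name` attribute); `wsm_presets()` returns a named list of them.
#' @export
#' @examples
#' wsm_preset("WSM3")
weighting_matrix <- function(name, weights) {
  if (length(weights) != 8L || any(!is.finite(weights)) || any(weights < 0))
    config_error("a weighting matrix needs 8 finite non-negative weights")
  w <- as.numeric(weights)
  names(w) <- c(EVIDENCE_SOURCES, "Cross")
  structure(w, name = as.character(name), class = "crossrank_wsm")
}

#' @rdname weighting_matrix
#' @export
wsm_presets <- function() {
  rows <- list(
    WSM1  = c(0.5, 0.5, 1, 1, 0.5, 0.5, 0.5, 1),
    WSM2  = c(0.5, 0.5, 1, 1, 0.5, 0.5, 0.5, 0.5),
    WSM3  = c(0.5, 0.5, 0.5, 1, 0.5, 0.5, 0.5, 0.5),
    WSM4  = c(0.5, 0.5, 1, 1, 1, 0.5, 0.5, 0.5),
    WSM5  = c(1, 1, 1, 1, 0.5, 0.5, 0.5, 0.5),
    WSM6  = c(1, 1, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5),
    WSM7  = c(1, 1, 1, 1, 1, 0.5, 0.5, 0.5),
    WSM8  = c(0.5, 0.5, 0.5, 1, 0.5, 0.5, 0.5, 1),
    WSM9  = c(1, 1, 1, 1, 1, 1, 1, 1),
    WSM10 = c(1, 1, 1, 1, 1, 1, 1, 0.5)
  )
  mapply(weighting_matrix, names(rows), rows, SIMPLIFY = FALSE)
}

#' @rdname weighting_matrix
#' @export
wsm_preset <- function(name) {
  presets <- wsm_presets()
  if (!name %in% names(presets))
    config_error("unknown preset '%s' (expected WSM1..WSM10)", name)
  presets[[name]]
}

#' @export
print.crossrank_wsm <- function(x, ...) {
  cat(sprintf("Weighting matrix %s\n", attr(x, "name")))
  print(unclass(x))
  invisible(x)
}

#' Score evidence profiles under a weighting matrix
#'
#' `score_profiles()` returns the weighted evidence score for every row
#' of a profile table; `score_gene()` scores a single profile row.
#'
#' @param profiles Profile `data.frame` from [build_profiles()].
#' @param wsm A `crossrank_wsm` (see [weighting_matrix()]).
#' @return Numeric score vector (one value per profile row).
#' @export
score_profiles <- function(profiles, wsm) {
  stopifnot(inherits(wsm, "crossrank_wsm"))
  ind <- as.matrix(profiles[, names(wsm), drop = FALSE]) * 1
  as.numeric(ind %*% as.numeric(wsm))
}

#' @rdname score_profiles
#' @param profile One-row profile `data.frame`.
#' @export
score_gene <- function(profile, wsm) {
  score_profiles(profile[1, , drop = FALSE], wsm)
}

#' Rank genes by weighted evidence score
#'
#' Scores every profile (by default only genes in the initial candidate
#' list) and sorts descending by score, breaking ties lexicographically
#' by gene symbol so the ordering is deterministic.
#'
#' @inheritParams score_profiles
#' @param restrict_initial If `TRUE` (default) only genes with
#'   `in_initial_list` are scored.
#' @return A `data.frame` `gene_id`, `symbol`, `score` plus the
#'   indicator columns, ordered by decreasing score.
#' @export
rank_genes <- function(profiles, wsm, restrict_initial = TRUE) {
  if (!nrow(profiles)) config_error("no profiles to rank")
  keep <- if (restrict_initial) profiles$in_initial_list else
    rep(TRUE, nrow(profiles))
  scored <- profiles[keep, , drop = FALSE]
  scored$score <- score_profiles(scored, wsm)
  ord <- order(-scored$score, scored$symbol, method = "radix")
  scored <- scored[ord, , drop = FALSE]
  rownames(scored) <- NULL
  scored[, c("gene_id", "symbol", "score", names(wsm), "in_initial_list")]
}

#' Tabulate the score distribution
#'
#' Counts genes per exact score value (preset weights make scores
#' multiples of 0.5). Custom weights are binned to `bin_width` after
#' rounding to a 1e-9 tolerance.
#'
#' @param scores Ranked gene `data.frame` from [rank_genes()] (or any
#'   `data.frame` with a `score` column).
#' @param bin_width Bin width; default 0.5.
#' @return A `data.frame` `score`, `n_genes` (ascending by score).
#'   Counts always sum to `nrow(scores)`.
#' @export
score_distribution <- function(scores, bin_width = 0.5) {
  if (bin_width <= 0) config_error("bin_width must be > 0")
  if (!nrow(scores))
    return(data.frame(score = numeric(0), n_genes = integer(0)))
  binned <- round(scores$score / bin_width + 1e-9) * bin_width
  tab <- table(binned)
  data.frame(score = as.numeric(names(tab)),
             n_genes = as.integer(tab))
}

#' Select top-scoring genes
#'
#' @param scores Ranked gene `data.frame` from [rank_genes()].
#' @param threshold Score threshold.
#' @param mode `"ge"` keeps genes with score >= threshold; `"eq"`
#'   keeps genes with score == threshold (1e-9 float tolerance).
#' @return The selected rows, in rank order.
#' @export
select_top <- function(scores, threshold, mode = c("ge", "eq")) {
  mode <- match.arg(mode)
  tol <- 1e-9
  keep <- if (mode == "ge") scores$score >= threshold - tol
          else abs(scores$score - threshold) <= tol
  out <- scores[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
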