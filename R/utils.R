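#' Evaluate an expression under a local RNG seed
#'
#' Runs `code` with the RNG seeded to `seed`, restoring the caller's
#' RNG state afterwards so seeded generators do not perturb user code.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Derive a stage-specific seed from a global seed
#'
#' Fans a single pipeline seed out into per-stage seeds by hashing the
#' stage name, so stages can be re-run in isolation with the stream
#' they saw inside the full run. Result is always in `[1, 2^31 - 2]`.
#'
#' @param seed Integer global seed.
#' @param stage Character stage label.
#' @return Integer seed.
#' @export
#' @examples
#' derive_seed(1, "gwas") != derive_seed(1, "evidence")
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 2147483647
  as.integer((abs(seed) * 48271 + h) %% 2147483646 + 1)
}

# Internal: stop() with a consistent prefix for user/config errors.
config_error <- function(...) stop(sprintf(...), call. = FALSE)

# Internal: gene length in bp under 1-based inclusive coordinates.
gene_lengths <- function(gene_table) {
  gene_table$end - gene_table$start + 1
}

# Internal: GRanges view of a gene table (optionally flank-extended,
# clipped at position 1).
genes_as_granges <- function(gene_table, flank_bp = 0) {
  GenomicRanges::GRanges(
    seqnames = gene_table$chrom,
    ranges = IRanges::IRanges(
      start = pmax(1L, gene_table$start - flank_bp),
      end = gene_table$end + flank_bp
    )
  )
}
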