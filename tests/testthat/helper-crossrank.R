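# Shared fixtures and independent oracles for the test suite.

# Hand-built 5-gene toy universe on two chromosomes.
toy_gene_table <- function() {
  data.frame(
    gene_id = c("G1", "G2", "G3", "G4", "G5"),
    symbol = c("ALPHA", "BRAVO", "CHARLIE", "DELTA", "ECHO"),
    chrom = c("chr1", "chr1", "chr1", "chr2", "chr2"),
    start = c(100000L, 115000L, 400000L, 50000L, 300000L),
    end = c(120000L, 140000L, 430000L, 80000L, 340000L),
    stringsAsFactors = FALSE)
}

# Reduced-scale simulation config used when many seeds are needed.
small_sim <- function(seed, ...) {
  sim_config(n_genes = 600, n_snps = 6000,
             evidence_counts = c(MuAc = 90, MuPref = 70, HuAlc = 55,
                                 HuAddChip = 35, Ce = 10, Dr = 18),
             seed = seed, ...)
}

# Random evidence profiles with the Cross flag derived by definition
# (independent of build_profiles).
random_profiles <- function(n, seed) {
  set.seed(seed)
  prof <- data.frame(gene_id = sprintf("R%03d", seq_len(n)),
                     symbol = sprintf("R%03d", seq_len(n)),
                     stringsAsFactors = FALSE)
  for (s in c("MuAc", "MuPref", "HuAlc", "HuAddChip", "HuLink", "Ce", "Dr"))
    prof[[s]] <- runif(n) < 0.3
  species <- cbind(prof$MuAc | prof$MuPref, prof$HuAlc | prof$HuAddChip,
                   prof$Ce, prof$Dr)
  prof$Cross <- rowSums(species) >= 2
  prof$in_initial_list <- prof$MuAc | prof$MuPref | prof$HuAlc
  prof
}

# Brute-force q-value oracle: double loop over the order statistics,
# max-rank convention for ties.
oracle_q <- function(p, pi0) {
  m <- length(p)
  vapply(seq_len(m), function(i) {
    js <- which(p >= p[i])
    min(1, min(pi0 * m * p[js] / vapply(js, function(j) sum(p <= p[j]), 0)))
  }, 0)
}

# Brute-force HWE exact-test oracle: enumerate every genotype triple
# with the observed allele counts and sum the probabilities of those no
# more likely than the observed configuration.
oracle_hwe <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  na <- 2 * n_aa + n_Aa
  if (min(na, 2 * n - na) == 0) return(1)
  configs <- list(); probs <- numeric(0)
  for (het in 0:min(na, 2 * n - na)) {
    aa2 <- na - het
    if (aa2 %% 2 != 0) next
    aa <- aa2 / 2
    AA <- n - het - aa
    if (AA < 0) next
    pr <- exp(lfactorial(n) - lfactorial(AA) - lfactorial(het) -
                lfactorial(aa) + het * log(2) -
                (lfactorial(2 * n) - lfactorial(na) -
                   lfactorial(2 * n - na)))
    configs[[length(configs) + 1]] <- c(AA, het, aa)
    probs <- c(probs, pr)
  }
  obs <- which(vapply(configs, function(x) x[2] == n_Aa, TRUE))
  sum(probs[probs <= probs[obs] * (1 + 1e-9)])
}

# Hypergeometric upper-tail oracle by full enumeration of draws:
# counts the C(N, n) subsets overlapping a fixed K-set in >= k elements.
oracle_hyper <- function(k, n, K, N) {
  draws <- utils::combn(N, n)
  mean(colSums(draws <= K) >= k)
}
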