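test_that("mean gene length is the arithmetic mean of spans", {
  gt <- data.frame(gene_id = c("a", "b", "c", "d", "e"),
                   symbol = c("a", "b", "c", "d", "e"), chrom = "chr1",
                   start = c(1L, 1L, 1L, 1L, 1L),
                   end = c(10000L, 30000L, 5000L, 70000L, 123L))
  expect_equal(mean_length("a", gt), 10000)
  expect_equal(mean_length(c("a", "b"), gt), 20000)
  expect_equal(mean_length(gt$gene_id, gt),
               mean(c(10000, 30000, 5000, 70000, 123)))
  expect_error(mean_length(character(0), gt), "empty")
  expect_error(mean_length("zz", gt), "absent")
})

test_that("matched sampling draws uniformly from the length-tolerance pool", {
  gt <- data.frame(gene_id = sprintf("g%02d", 1:30),
                   symbol = sprintf("g%02d", 1:30), chrom = "chr1",
                   start = rep(1L, 30),
                   end = c(rep(20000L, 20), rep(500000L, 10)))
  cfg <- perm_config(length_tol_bp = 1000)
  # all 20 short genes qualify; no duplicates
  set.seed(5)
  s <- sample_matched(gt, 5, 20000, cfg)
  expect_length(unique(s), 5)
  expect_true(all(s %in% gt$gene_id[1:20]))
  # pool of exactly n is returned whole
  s2 <- sample_matched(gt, 10, 500000, cfg)
  expect_setequal(s2, gt$gene_id[21:30])
  # inclusion frequencies uniform over the 20-gene pool
  set.seed(6)
  tallies <- table(factor(unlist(replicate(5000, sample_matched(
    gt, 5, 20000, cfg), simplify = FALSE)), levels = gt$gene_id[1:20]))
  gof <- stats::chisq.test(as.integer(tallies))
  expect_gt(gof$p.value, 0.01)
  # widening doubles the tolerance until the pool suffices
  s3 <- sample_matched(gt, 25, 20000, cfg)
  expect_gte(attr(s3, "widenings"), 1)
  expect_error(
    sample_matched(gt, 25, 20000,
                   perm_config(length_tol_bp = 1000,
                               widen_on_small_pool = FALSE)),
    "pool")
  # every matched draw stays inside the (possibly widened) tolerance
  lens <- gt$end - gt$start + 1
  for (i in 1:20) {
    d <- sample_matched(gt, 5, 20000, cfg)
    expect_true(all(abs(lens[match(d, gt$gene_id)] - 20000) <= 1000))
  }
})

test_that("degenerate universes give empirical p = 0 under strict comparison", {
  # every gene has the same length and every gene is in the observed
  # set, so each matched sample is the observed set itself
  gt <- data.frame(gene_id = c("d1", "d2"), symbol = c("d1", "d2"),
                   chrom = "chr1", start = c(1L, 50001L),
                   end = c(20000L, 70000L))
  snps <- data.frame(snp_id = sprintf("s%03d", 1:200), chrom = "chr1",
                     pos = rep(c(5000L, 55000L), 100),
                     p = ((1:200) / 200)^2)
  mp <- map_snps_to_genes(snps, gt, flank_bp = 0)
  scores <- data.frame(gene_id = c("d1", "d2"), symbol = c("d1", "d2"),
                       score = c(2, 2))
  pr <- permutation_pvalues(scores, mp, snps, gt,
                            perm_config(B = 10, thresholds = 2,
                                        eq_thresholds = numeric(0), seed = 1),
                            pi0_method = "fixed")
  pop <- pr$table[pr$table$observed_count > 0, ]
  expect_true(nrow(pop) > 0)
  expect_true(all(pop$p_emp == 0))
  expect_equal(pop$p_add_one, rep(1 / 11, nrow(pop)))
  # bins with zero observed SNPs are NA
  expect_true(all(is.na(pr$table$p_emp[pr$table$observed_count == 0])))
})

test_that("the observed rows of a report do not depend on B", {
  st <- simulate_study(small_sim(seed = 51))
  prof <- build_profiles(st$gene_table, st$evidence$sets)
  ranked <- rank_genes(prof, wsm_preset("WSM3"))
  mp <- map_snps_to_genes(st$snps, st$gene_table)
  obs_cols <- c("cutoff", "q_threshold", "n_snps", "observed_count",
                "observed_prop")
  r3 <- permutation_pvalues(ranked, mp, st$snps, st$gene_table,
                            perm_config(B = 3, seed = 2),
                            pi0_method = "fixed")
  r10 <- permutation_pvalues(ranked, mp, st$snps, st$gene_table,
                             perm_config(B = 10, seed = 99),
                             pi0_method = "fixed")
  expect_identical(r3$table[obs_cols], r10$table[obs_cols])
  expect_identical(r3$cutoffs, r10$cutoffs)
  # seeded determinism of the full report
  r3b <- permutation_pvalues(ranked, mp, st$snps, st$gene_table,
                             perm_config(B = 3, seed = 2),
                             pi0_method = "fixed")
  expect_identical(r3$table, r3b$table)
})

test_that("null permutation p-values are centred and planted signal is detected", {
  # exchangeable null: mean empirical p over populated cells near 1/2
  cfg <- sim_config(n_genes = 400, n_snps = 4000,
                    evidence_counts = c(MuAc = 60, MuPref = 45, HuAlc = 35,
                                        HuAddChip = 25, Ce = 8, Dr = 12),
                    planted_genes = NULL, seed = 61)
  st <- simulate_study(cfg)
  prof <- build_profiles(st$gene_table, st$evidence$sets)
  ranked <- rank_genes(prof, wsm_preset("WSM3"))
  mp <- map_snps_to_genes(st$snps, st$gene_table)
  pr <- permutation_pvalues(ranked, mp, st$snps, st$gene_table,
                            perm_config(B = 200, thresholds = c(0.5, 1),
                                        eq_thresholds = numeric(0),
                                        seed = 8),
                            pi0_method = "fixed")
  m <- mean(pr$table$p_emp, na.rm = TRUE)
  expect_gte(m, 0.35); expect_lte(m, 0.65)

  # planted signal: small empirical p at the most stringent populated bin
  st2 <- simulate_study(small_sim(seed = 62))
  prof2 <- build_profiles(st2$gene_table, st2$evidence$sets)
  ranked2 <- rank_genes(prof2, wsm_preset("WSM3"))
  mp2 <- map_snps_to_genes(st2$snps, st2$gene_table)
  pr2 <- permutation_pvalues(ranked2, mp2, st2$snps, st2$gene_table,
                             perm_config(B = 200, thresholds = 2,
                                         eq_thresholds = numeric(0),
                                         seed = 9),
                             pi0_method = "fixed")
  pop <- pr2$table[pr2$table$observed_count > 0, ]
  expect_lt(pop$p_emp[which.min(pop$q_threshold)], 0.05)
})

test_that("matrix selection ranks by min q with auditable tie-breaks", {
  mk_report <- function(min_q, count05, p_emp) {
    structure(list(
      table = data.frame(cutoff = ">=2", q_threshold = c(0.9, 0.5),
                         n_snps = 100L, observed_count = c(50L, count05),
                         observed_prop = c(0.5, count05 / 100),
                         perm_mean_prop = 0.3,
                         p_emp = c(0.5, p_emp), p_add_one = NA),
      cutoffs = data.frame(cutoff = ">=2", n_genes = 10L, n_snps = 100L,
                           min_q = min_q),
      cfg = perm_config()), class = "crossrank_perm_report")
  }
  one <- list(A = mk_report(0.35, 5L, 0.1))
  expect_identical(select_best_matrix(one)$best, "A")
  two <- list(LOW = mk_report(0.35, 5L, 0.1), HIGH = mk_report(0.60, 9L, 0.01))
  sel <- select_best_matrix(two)
  expect_identical(sel$best, "LOW")
  expect_identical(sel$ranking$wsm, c("LOW", "HIGH"))
  # input order does not change the winner
  expect_identical(select_best_matrix(rev(two))$best, "LOW")
  # tie on min q broken by SNPs with q < 0.5
  tie <- list(FEW = mk_report(0.35, 2L, 0.1), MANY = mk_report(0.35, 9L, 0.5))
  expect_identical(select_best_matrix(tie)$best, "MANY")
  expect_error(select_best_matrix(list()), "no permutation reports")
})
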