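test_that("marker statistics: MAF pooling, monomorphic convention, call rate", {
  s <- snp_stats(control_counts = c(25, 50, 25))
  expect_equal(s$maf, 0.5)
  s <- snp_stats(control_counts = c(100, 0, 0))
  expect_equal(s$maf, 0)
  expect_equal(s$hwe_p, 1)
  s <- snp_stats(case_counts = c(40, 20, 0), control_counts = c(30, 10, 0),
                 n_cases = 60, n_controls = 50)
  # pooled minor allele: (20 + 10) / (2 * 100)
  expect_equal(s$maf, 30 / 200)
  expect_equal(s$call_rate, 100 / 110)
  expect_error(snp_stats(case_counts = c(0, 0, 0),
                         control_counts = c(0, 0, 0)), "all-zero")
  expect_error(snp_stats(), "required")
})

test_that("the HWE exact test matches a brute-force enumeration oracle", {
  cases <- list(c(3, 5, 2), c(10, 1, 10), c(0, 20, 0), c(7, 0, 3),
                c(12, 12, 1), c(1, 1, 1), c(50, 21, 4))
  for (g in cases) {
    expect_equal(hwe_exact_test(g[1], g[2], g[3]),
                 oracle_hwe(g[1], g[2], g[3]),
                 tolerance = 1e-12, info = paste(g, collapse = ","))
  }
  expect_equal(hwe_exact_test(100, 0, 0), 1)
  expect_error(hwe_exact_test(0, 0, 0), "all-zero")
})

test_that("QC filtering applies the three rules with first-fail attribution", {
  snps <- data.frame(
    snp_id = paste0("rs", 1:6), chrom = "chr1", pos = 1:6 * 1000,
    p = rep(0.5, 6),
    call_rate = c(0.99, 0.94, 0.99, 0.99, 0.93, 0.99),
    maf = c(0.2, 0.2, 0.005, 0.2, 0.005, 0.2),
    hwe_p = c(0.5, 0.5, 0.5, 1e-9, 1e-9, 0.5))
  res <- qc_filter(snps)
  expect_identical(res$snps$snp_id, c("rs1", "rs6"))
  # rs2 fails call rate; rs3 MAF; rs4 HWE; rs5 call rate (first rule wins)
  expect_identical(res$report$excluded_call_rate, 2L)
  expect_identical(res$report$excluded_maf, 1L)
  expect_identical(res$report$excluded_hwe, 1L)
  expect_identical(res$report$n_pass + res$report$excluded_call_rate +
                     res$report$excluded_maf + res$report$excluded_hwe,
                   res$report$n_input)
  # idempotent; clean input passes unchanged in order
  res2 <- qc_filter(res$snps)
  expect_identical(res2$snps, res$snps)
  # boundary values from the QC contract
  edge <- data.frame(snp_id = c("a", "b"), chrom = "chr1", pos = c(1, 2),
                     p = 0.5, call_rate = c(0.95, 0.99),
                     maf = c(0.01, 0.009), hwe_p = 0.5)
  rese <- qc_filter(edge)
  expect_identical(rese$snps$snp_id, "a")   # exactly at both thresholds: pass
  expect_identical(rese$report$excluded_maf, 1L)
})

test_that("QC statistics are recomputed from genotype counts when absent", {
  snps <- data.frame(
    snp_id = c("ok", "rare"), chrom = "chr1", pos = c(1, 2), p = 0.5,
    case_AA = c(50, 99), case_Aa = c(40, 1), case_aa = c(10, 0),
    ctrl_AA = c(45, 100), ctrl_Aa = c(45, 0), ctrl_aa = c(10, 0))
  res <- qc_filter(snps)
  expect_identical(res$snps$snp_id, "ok")
  expect_identical(res$report$excluded_maf, 1L)
})

test_that("allelic chi-square test matches hand evaluation and stays in range", {
  expect_equal(allelic_test(c(30, 10), c(30, 10)), 1)
  # chi-square = 20 by hand for (30,10) vs (10,30)
  expect_equal(allelic_test(c(30, 10), c(10, 30)),
               stats::pchisq(20, 1, lower.tail = FALSE))
  expect_equal(allelic_test(c(0, 40), c(0, 30)), 1)   # zero margin
  expect_error(allelic_test(c(-1, 2), c(1, 1)), "negative")
  set.seed(4)
  ps <- replicate(1000, allelic_test(rmultinom(1, 50, c(0.5, 0.5)),
                                     rmultinom(1, 50, c(0.5, 0.5))))
  expect_true(all(ps > 0 & ps <= 1))
})

test_that("allelic test p-values are approximately uniform under the null", {
  set.seed(9)
  ps <- replicate(1500, {
    q <- runif(1, 0.2, 0.8)
    allelic_test(rmultinom(1, 800, c(q, 1 - q)),
                 rmultinom(1, 600, c(q, 1 - q)))
  })
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif")$p.value), 0.01)
})

test_that("SNP-to-gene mapping uses an inclusive 10 kb flank window", {
  gt <- data.frame(gene_id = c("GA", "GB", "GC"),
                   symbol = c("GA", "GB", "GC"), chrom = "chr1",
                   start = c(100000L, 118000L, 500000L),
                   end = c(120000L, 150000L, 520000L))
  snps <- data.frame(snp_id = c("s_in", "s_out", "s_both", "s_none"),
                     chrom = "chr1",
                     pos = c(90001L, 89999L, 119000L, 300000L),
                     p = c(0.1, 0.2, 0.3, 0.4))
  mp <- map_snps_to_genes(snps, gt, flank_bp = 10000)
  expect_true(any(mp$map$snp_id == "s_in" & mp$map$gene_id == "GA"))
  expect_false("s_out" %in% mp$map$snp_id)
  # a SNP inside two overlapping windows maps to both genes
  expect_setequal(mp$map$gene_id[mp$map$snp_id == "s_both"], c("GA", "GB"))
  expect_false("s_none" %in% mp$map$snp_id)
  expect_equal(mp$mapped_fraction, 2 / 4)
  # per-gene index and per-SNP map encode the same relation
  rebuilt <- do.call(rbind, lapply(names(mp$by_gene), function(g)
    data.frame(snp_id = mp$by_gene[[g]], gene_id = g)))
  expect_setequal(paste(rebuilt$snp_id, rebuilt$gene_id),
                  paste(mp$map$snp_id, mp$map$gene_id))
  expect_setequal(snps_for_genes(mp, c("GA", "GB")), c("s_in", "s_both"))
})
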