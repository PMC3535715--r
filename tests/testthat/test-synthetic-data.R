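test_that("the generator is fully deterministic under a fixed seed", {
  cfg <- small_sim(seed = 7)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$gene_table, s2$gene_table)
  expect_identical(s1$evidence$sets, s2$evidence$sets)
  expect_identical(s1$snps, s2$snps)
  expect_identical(s1$sets, s2$sets)
  # and byte-identical on disk
  d1 <- tempfile(); d2 <- tempfile()
  simulate_study(cfg, d1); simulate_study(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("gene universe respects size, coordinates and the length law", {
  empty <- generate_gene_universe(sim_config(n_genes = 0))
  expect_identical(nrow(empty), 0L)
  expect_true(all(c("gene_id", "symbol", "chrom", "start", "end") %in%
                    names(empty)))

  cfg <- sim_config(n_genes = 2000,
                    gene_length_law = list(law = "uniform",
                                           min = 10000, max = 200000),
                    seed = 11)
  gt <- generate_gene_universe(cfg)
  expect_identical(nrow(gt), 2000L)
  expect_false(any(duplicated(gt$gene_id)))
  expect_true(all(gt$end >= gt$start))
  lens <- gt$end - gt$start + 1
  se <- (200000 - 10000) / sqrt(12) / sqrt(2000)
  expect_lt(abs(mean(lens) - 105000), 3 * se)
  # every gene fits its chromosome
  expect_true(all(gt$end <= cfg$chrom_layout[gt$chrom]))
})

test_that("disallowing overlap lays genes out disjointly or errors on infeasible layouts", {
  cfg <- sim_config(n_genes = 150, allow_overlap = FALSE,
                    chrom_layout = c(chrA = 5e6, chrB = 5e6),
                    gene_length_law = list(law = "fixed", length = 20000),
                    seed = 3)
  gt <- generate_gene_universe(cfg)
  for (cn in unique(gt$chrom)) {
    g <- gt[gt$chrom == cn, ]
    g <- g[order(g$start), ]
    expect_true(all(diff(g$start) > (g$end - g$start + 1)[-nrow(g)] - 1))
    expect_true(all(g$start[-1] > g$end[-nrow(g)]))
  }
  infeasible <- sim_config(n_genes = 200, allow_overlap = FALSE,
                           chrom_layout = c(chrTiny = 1e6),
                           gene_length_law = list(law = "fixed",
                                                  length = 20000),
                           seed = 3)
  expect_error(generate_gene_universe(infeasible), "chrTiny")
})

test_that("evidence generation honours counts, zero case and forced overlap", {
  cfg0 <- sim_config(evidence_counts = c(MuAc = 0, MuPref = 0, HuAlc = 0,
                                         HuAddChip = 0, Ce = 0, Dr = 0),
                     n_linkage_intervals = 0, seed = 5)
  gt0 <- generate_gene_universe(cfg0)
  ev0 <- generate_evidence(gt0, cfg0)
  expect_identical(length(ev0$sets), 7L)
  expect_true(all(lengths(ev0$sets) == 0))
  expect_length(ev0$truth$multi_species, 0)

  cfg1 <- sim_config(evidence_counts = c(MuAc = 60, MuPref = 40, HuAlc = 30,
                                         HuAddChip = 20, Ce = 10, Dr = 15),
                     cross_species_overlap = 1.0, seed = 9)
  gt1 <- generate_gene_universe(cfg1)
  ev1 <- generate_evidence(gt1, cfg1)
  non_worm <- unique(unlist(ev1$sets[c("MuAc", "MuPref", "HuAlc",
                                       "HuAddChip", "Dr")]))
  expect_true(all(ev1$sets$Ce %in% non_worm))
  # counts are honoured exactly
  expect_identical(length(ev0$sets[["MuAc"]]), 0L)
  expect_identical(length(ev1$sets$Ce), 10L)
})

test_that("realized cross-species overlap matches the configured fraction", {
  ovl <- vapply(1:20, function(s) {
    cfg <- sim_config(evidence_counts = c(MuAc = 220, MuPref = 170,
                                          HuAlc = 130, HuAddChip = 87,
                                          Ce = 30, Dr = 50),
                      cross_species_overlap = 0.3, seed = s)
    gt <- generate_gene_universe(cfg)
    ev <- generate_evidence(gt, cfg)
    list_sources <- c("MuAc", "MuPref", "HuAlc", "HuAddChip", "Ce", "Dr")
    n_evidence <- length(unique(unlist(ev$sets[list_sources])))
    length(ev$truth$multi_species) / n_evidence
  }, 0)
  expect_gte(mean(ovl), 0.27)
  expect_lte(mean(ovl), 0.33)
})

test_that("worm and fly lists are emitted in native ids with working ortholog maps", {
  cfg <- small_sim(seed = 13)
  gt <- generate_gene_universe(cfg)
  ev <- generate_evidence(gt, cfg)
  expect_true(all(startsWith(ev$worm_ids, "cel-")))
  expect_true(all(startsWith(ev$fly_ids, "dmel-")))
  f <- tempfile()
  write_evidence_list(ev$worm_ids, f)
  got <- load_evidence_list(f, "worm", ev$ortholog_maps$Ce)
  expect_setequal(got$genes, ev$sets$Ce)
  unlink(f)
})

test_that("null GWAS p-values are uniform and planted signal is right-skewed", {
  cfg <- sim_config(n_snps = 50000, planted_genes = NULL, seed = 21)
  gt <- generate_gene_universe(cfg)
  gw <- generate_gwas(gt, NULL, cfg)
  frac <- mean(gw$snps$p < 0.05)
  expect_gte(frac, 0.045); expect_lte(frac, 0.055)
  expect_true(all(gw$truth$snp_labels$status == "null"))

  # a = 1 makes planted p-values uniform in law
  ks_ok <- vapply(1:20, function(s) {
    cfg1 <- small_sim(seed = s, planted_effect = 1.0)
    st <- simulate_study(cfg1)
    alt <- st$truth$snp_labels$status == "alt"
    suppressWarnings(stats::ks.test(st$snps$p[alt], "punif")$p.value) > 0.01
  }, TRUE)
  expect_gte(sum(ks_ok), 18)

  # a = 0.2 dominates the null stochastically in every seeded run
  dominated <- vapply(1:20, function(s) {
    st <- simulate_study(small_sim(seed = 100 + s, planted_effect = 0.2))
    alt <- st$truth$snp_labels$status == "alt"
    median(st$snps$p[alt]) < median(st$snps$p[!alt])
  }, TRUE)
  expect_true(all(dominated))
})

test_that("null marker panels yield calibrated q-values downstream", {
  # under the global null P(min q <= alpha) ~ alpha, so min q should
  # clear a 0.05 floor in about 95% of seeds
  clear <- vapply(1:20, function(s) {
    cfg <- sim_config(n_snps = 10000, planted_genes = NULL,
                      defect_rate = 0, seed = 300 + s)
    gt <- generate_gene_universe(cfg)
    gw <- generate_gwas(gt, NULL, cfg)
    min(storey_q(gw$snps$p)$q) > 0.05
  }, TRUE)
  expect_gte(sum(clear), 16)
})

test_that("genotype-count emission is consistent with the QC columns", {
  cfg <- sim_config(n_genes = 100, n_snps = 500, emit_genotypes = TRUE,
                    evidence_counts = c(MuAc = 15, MuPref = 12, HuAlc = 9,
                                        HuAddChip = 6, Ce = 2, Dr = 3),
                    set_size_range = c(5, 30),
                    defect_rate = 0, seed = 17)
  st <- simulate_study(cfg)
  expect_true(all(c("case_AA", "ctrl_aa") %in% names(st$snps)))
  n_typed <- rowSums(st$snps[, c("ctrl_AA", "ctrl_Aa", "ctrl_aa")])
  expect_equal(n_typed, round(cfg$n_controls * st$snps$call_rate))
  # pooled allele frequency tracks the emitted MAF column
  i <- which.max(st$snps$maf)
  s <- snp_stats(unlist(st$snps[i, c("case_AA", "case_Aa", "case_aa")]),
                 unlist(st$snps[i, c("ctrl_AA", "ctrl_Aa", "ctrl_aa")]))
  expect_lt(abs(s$maf - st$snps$maf[i]), 0.05)
})

test_that("annotation sets carry the designated planted enrichment", {
  cfg <- small_sim(seed = 23, planted_set_exact = TRUE)
  st <- simulate_study(cfg)
  designated <- attr(st$sets, "designated")
  expect_identical(sort(st$sets[[designated]]), sort(st$truth$planted))
  res <- enrich(st$truth$planted, st$sets, st$gene_table$gene_id)
  expect_identical(res$set[1], designated)

  # a single set equal to the whole universe can never be enriched
  whole <- list(ALL = st$gene_table$gene_id)
  res_all <- enrich(st$truth$planted, whole, st$gene_table$gene_id)
  expect_equal(res_all$p, 1)

  expect_error(
    generate_annotations(toy_gene_table(), st$truth,
                         sim_config(n_genes = 5, set_size_range = c(5, 50))),
    "universe")
})
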