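#' Pipeline configuration
#'
#' Collects every stage configuration for [run_pipeline()]. The master
#' `seed` is fanned out to stage-specific derived seeds (see
#' [derive_seed()]) so stages can be re-run in isolation.
#'
#' @param sim A [sim_config()] used when no real inputs are supplied;
#'   its seed is overridden by `seed`.
#' @param qc A [qc_config()].
#' @param perm A [perm_config()]; its seed is derived from `seed` per
#'   weighting matrix.
#' @param wsms Character vector of preset names (or a named list of
#'   [weighting_matrix()] objects) to evaluate.
#' @param top_threshold Score cutoff defining the top gene list of the
#'   selected matrix (default 2).
#' @param fdr_method `"storey"`, `"storey-fixed"` or `"bh"`.
#' @param seed Master integer seed.
#' @param inputs Optional named list of file paths for a real-data
#'   run: `genes`, `MuAc`, `MuPref`, `HuAlc`, `HuAddChip`, `Ce`,
#'   `Dr`, `Ce_map`, `Dr_map`, `linkage`, `snps`, `gmt`. When given,
#'   the simulation stage is skipped.
#' @return A `crossrank_pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(), qc = qc_config(),
                            perm = perm_config(),
                            wsms = paste0("WSM", 1:10),
                            top_threshold = 2,
                            fdr_method = c("storey", "storey-fixed", "bh"),
                            seed = 1L, inputs = NULL) {
  fdr_method <- match.arg(fdr_method)
  structure(list(sim = sim, qc = qc, perm = perm, wsms = wsms,
                 top_threshold = top_threshold, fdr_method = fdr_method,
                 seed = as.integer(seed), inputs = inputs),
            class = "crossrank_pipeline_config")
}

# Internal: storey_q() arguments implied by the configured FDR method.
fdr_args <- function(cfg) {
  switch(cfg$fdr_method,
         storey = list(pi0_method = "smoother"),
         `storey-fixed` = list(pi0_method = "fixed"),
         bh = list(pi0_method = "bh"))
}

# Internal: resolve configured matrices to crossrank_wsm objects.
resolve_wsms <- function(wsms) {
  if (is.character(wsms)) {
    out <- lapply(wsms, wsm_preset)
    names(out) <- wsms
    return(out)
  }
  stopifnot(is.list(wsms), !is.null(names(wsms)))
  out <- lapply(wsms, function(w) {
    if (!inherits(w, "crossrank_wsm")) config_error("invalid weighting matrix")
    w
  })
  out
}

#' Run the full ranking-and-evaluation pipeline
#'
#' Executes simulate (skipped when real inputs are supplied) ->
#' integrate -> rank -> QC -> map -> q-value -> permute -> select ->
#' enrich, aggregating every stage's result in one report. A stage
#' failure aborts with the stage name; if `outdir` is given, partial
#' results are retained under a `failed/` prefix.
#'
#' @param cfg A [pipeline_config()].
#' @param outdir Optional directory: on success nothing is written
#'   here by this function (use [write_report()]); on failure the
#'   partial report is written under `file.path(outdir, "failed")`.
#' @return A `crossrank_report` list with sections `config`, `data`,
#'   `qc`, `mapping`, `global_q`, `distributions`, `permutation`,
#'   `selection`, `top_genes`, `enrichment`, `log`.
#' @export
run_pipeline <- function(cfg, outdir = NULL) {
  stopifnot(inherits(cfg, "crossrank_pipeline_config"))
  report <- structure(list(config = list(
    wsms = if (is.character(cfg$wsms)) cfg$wsms else names(cfg$wsms),
    top_threshold = cfg$top_threshold, fdr_method = cfg$fdr_method,
    seed = cfg$seed, B = cfg$perm$B)), class = "crossrank_report")
  log <- character(0)
  t0 <- proc.time()[["elapsed"]]
  note <- function(stage, msg) {
    log <<- c(log, sprintf("[%8.2fs] %s: %s",
                           proc.time()[["elapsed"]] - t0, stage, msg))
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      report$log <- c(log, sprintf("stage %s FAILED: %s", stage,
                                   conditionMessage(e)))
      if (!is.null(outdir)) {
        fdir <- file.path(outdir, "failed")
        try(write_report(report, fdir), silent = TRUE)
      }
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  fa <- fdr_args(cfg)

  # -- data ------------------------------------------------------------
  dat <- run_stage("data", {
    if (is.null(cfg$inputs)) {
      sim <- cfg$sim
      sim$seed <- cfg$seed
      study <- simulate_study(sim)
      note("data", sprintf("simulated %d genes, %d SNPs, %d gene sets",
                           nrow(study$gene_table), nrow(study$snps),
                           length(study$sets)))
      list(gene_table = study$gene_table, sets = study$evidence$sets,
           snps = study$snps, gmt = study$sets, truth = study$truth)
    } else {
      inp <- cfg$inputs
      gene_table <- read_gene_table(inp$genes)
      sets <- list(
        MuAc = load_evidence_list(inp$MuAc, "human")$genes,
        MuPref = load_evidence_list(inp$MuPref, "human")$genes,
        HuAlc = load_evidence_list(inp$HuAlc, "human")$genes,
        HuAddChip = load_evidence_list(inp$HuAddChip, "human")$genes,
        HuLink = assign_linkage(gene_table, read_linkage_bed(inp$linkage)),
        Ce = load_evidence_list(inp$Ce, "worm", inp$Ce_map)$genes,
        Dr = load_evidence_list(inp$Dr, "fly", inp$Dr_map)$genes)
      gmt <- if (!is.null(inp$gmt)) read_gmt(inp$gmt) else NULL
      note("data", sprintf("read %d genes, %d SNPs (simulation skipped)",
                           nrow(gene_table),
                           nrow(read_snp_table(inp$snps))))
      list(gene_table = gene_table, sets = sets,
           snps = read_snp_table(inp$snps), gmt = gmt, truth = NULL)
    }
  })
  report$data <- list(n_genes = nrow(dat$gene_table),
                      n_snps = nrow(dat$snps),
                      simulated = is.null(cfg$inputs))

  # -- integrate -------------------------------------------------------
  profiles <- run_stage("integrate", {
    p <- build_profiles(dat$gene_table, dat$sets)
    note("integrate", sprintf("%d profiles, %d in initial list",
                              nrow(p), sum(p$in_initial_list)))
    p
  })
  report$integrate <- list(n_initial = sum(profiles$in_initial_list))

  # -- qc + map --------------------------------------------------------
  qcres <- run_stage("qc", {
    r <- qc_filter(dat$snps, cfg$qc)
    note("qc", sprintf("%d of %d SNPs pass", r$report$n_pass,
                       r$report$n_input))
    r
  })
  report$qc <- qcres$report
  mapping <- run_stage("map", {
    m <- map_snps_to_genes(qcres$snps, dat$gene_table)
    note("map", sprintf("%.1f%% of SNPs mapped to genes",
                        100 * m$mapped_fraction))
    m
  })
  report$mapping <- list(n_pairs = nrow(mapping$map),
                         mapped_fraction = mapping$mapped_fraction)

  # -- global q-values -------------------------------------------------
  report$global_q <- run_stage("qvalue", {
    qv_all <- do.call(storey_q, c(list(qcres$snps$p), fa))
    mapped_ids <- unique(mapping$map$snp_id)
    qv_map <- do.call(storey_q, c(
      list(qcres$snps$p[qcres$snps$snp_id %in% mapped_ids]), fa))
    note("qvalue", sprintf("min q %.3f (all pass), %.3f (mapped)",
                           min(qv_all$q), min(qv_map$q)))
    list(min_q_all = min(qv_all$q), min_q_mapped = min(qv_map$q),
         pi0_all = qv_all$pi0, n_all = qv_all$n, n_mapped = qv_map$n)
  })

  # -- rank + permute per matrix --------------------------------------
  wsms <- resolve_wsms(cfg$wsms)
  ranked <- list(); report$distributions <- list(); perm_reports <- list()
  for (nm in names(wsms)) {
    ranked[[nm]] <- run_stage("rank", rank_genes(profiles, wsms[[nm]]))
    report$distributions[[nm]] <- score_distribution(ranked[[nm]])
    perm_reports[[nm]] <- run_stage("permute", {
      pc <- cfg$perm
      pc$seed <- derive_seed(cfg$seed, paste0("perm-", nm))
      do.call(permutation_pvalues,
              c(list(ranked[[nm]], mapping, qcres$snps, dat$gene_table, pc),
                fa))
    })
    note("permute", sprintf("%s: observed min q %.3f", nm,
                            suppressWarnings(
                              min(perm_reports[[nm]]$cutoffs$min_q,
                                  na.rm = TRUE))))
  }
  report$permutation <- perm_reports

  # -- select + top + enrich ------------------------------------------
  sel <- run_stage("select", select_best_matrix(perm_reports))
  note("select", sprintf("best matrix: %s", sel$best))
  report$selection <- sel
  top <- run_stage("top", select_top(ranked[[sel$best]],
                                     cfg$top_threshold, "ge"))
  note("top", sprintf("%d genes at score >= %s under %s", nrow(top),
                      cfg$top_threshold, sel$best))
  report$top_genes <- top[, c("gene_id", "symbol", "score")]
  report$enrichment <- run_stage("enrich", {
    if (is.null(dat$gmt)) NULL else {
      e <- enrich(top$gene_id, dat$gmt, dat$gene_table$gene_id)
      note("enrich", sprintf("%d sets tested, top p %.3g", nrow(e),
                             if (nrow(e)) e$p[1] else NA))
      e
    }
  })
  report$truth <- dat$truth
  report$log <- log
  report
}

#' Write a pipeline report to disk
#'
#' Emits TSV tables (score distributions, permutation tables, matrix
#' selection, top genes, enrichment), one machine-readable
#' `summary.json`, a plain-text `narrative.txt` (selected matrix, top
#' gene count, min q per cutoff, one line per configured matrix), and
#' `log.txt`. All files except `log.txt` are byte-deterministic for a
#' fixed config and seed.
#'
#' @param report A `crossrank_report` from [run_pipeline()] (possibly
#'   partial).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, f) utils::write.table(df, file.path(dir, f), sep = "\t",
                                          quote = FALSE, row.names = FALSE)
  if (length(report$distributions)) {
    dist <- do.call(rbind, lapply(names(report$distributions), function(nm)
      cbind(wsm = nm, report$distributions[[nm]])))
    w(dist, "score_distributions.tsv")
  }
  if (length(report$permutation)) {
    perm <- do.call(rbind, lapply(names(report$permutation), function(nm)
      cbind(wsm = nm, report$permutation[[nm]]$table)))
    w(perm, "permutation_pvalues.tsv")
    cuts <- do.call(rbind, lapply(names(report$permutation), function(nm)
      cbind(wsm = nm, report$permutation[[nm]]$cutoffs)))
    w(cuts, "qbin_min_q.tsv")
  }
  if (!is.null(report$selection)) w(report$selection$ranking, "selection.tsv")
  if (!is.null(report$top_genes)) w(report$top_genes, "top_genes.tsv")
  if (!is.null(report$enrichment) && nrow(report$enrichment))
    w(report$enrichment, "enrichment.tsv")

  summary <- list(
    config = report$config,
    data = report$data,
    integrate = report$integrate,
    qc = report$qc,
    mapping = report$mapping,
    global_q = report$global_q,
    selection = if (!is.null(report$selection))
      list(best = report$selection$best, ranking = report$selection$ranking),
    n_top_genes = if (!is.null(report$top_genes)) nrow(report$top_genes),
    min_q_per_cutoff = if (!is.null(report$selection) &&
                           !is.null(report$permutation))
      report$permutation[[report$selection$best]]$cutoffs,
    top_enrichment_p = if (!is.null(report$enrichment) &&
                           nrow(report$enrichment))
      report$enrichment$p[1]
  )
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       dataframe = "columns", na = "null")

  lines <- character(0)
  if (!is.null(report$selection)) {
    lines <- c(lines, sprintf("Selected weighting matrix: %s",
                              report$selection$best))
    rk <- report$selection$ranking
    lines <- c(lines, sprintf("  %s: min q %s (SNPs with q<0.5: %d)",
                              rk$wsm, format(rk$min_q, digits = 4),
                              rk$n_q_lt_05))
  }
  if (!is.null(report$top_genes))
    lines <- c(lines, sprintf("Top gene list: %d genes",
                              nrow(report$top_genes)))
  if (!is.null(report$selection) && !is.null(report$permutation)) {
    cuts <- report$permutation[[report$selection$best]]$cutoffs
    lines <- c(lines, sprintf("Min q at cutoff %s: %s (%d SNPs)",
                              cuts$cutoff, format(cuts$min_q, digits = 4),
                              cuts$n_snps))
  }
  writeLines(lines, file.path(dir, "narrative.txt"))
  writeLines(c(format(Sys.time()), report$log), file.path(dir, "log.txt"))
  invisible(dir)
}

#' Read back a written report summary
#'
#' @param dir Directory written by [write_report()].
#' @return Parsed `summary.json` as a list.
#' @export
read_report_summary <- function(dir) {
  jsonlite::read_json(file.path(dir, "summary.json"), simplifyVector = TRUE)
}
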