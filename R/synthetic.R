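#' Configuration for the synthetic study generator
#'
#' Bundles every knob of the synthetic data generator. The defaults
#' describe the desk-scale study emulated throughout the package: a
#' 2000-gene universe on four chromosomes with lognormal gene lengths,
#' six evidence list sources with a 0.3 cross-species overlap, three
#' multi-megabase linkage intervals, and a 20000-marker GWAS panel
#' with association signal planted in the genes that rank at or above
#' score 2 under a designated weighting matrix (`Beta(a, 1)`
#' alternative p-values, a = 0.2). Case/control sample counts default
#' to 1205/700 and are only used when genotype counts are emitted.
#'
#' @param n_genes Number of genes in the universe.
#' @param chrom_layout Named numeric vector of chromosome lengths (bp).
#' @param gene_length_law List `law` (`"lognormal"`, `"uniform"` or
#'   `"fixed"`) plus its parameters (`meanlog`/`sdlog`, `min`/`max`,
#'   or `length`), in bp.
#' @param allow_overlap May genes on a chromosome overlap? Real
#'   genomes do; disable for clean toy fixtures.
#' @param evidence_counts Named counts for the six list sources
#'   (`MuAc`, `MuPref`, `HuAlc`, `HuAddChip`, `Ce`, `Dr`).
#' @param cross_species_overlap Target fraction of evidence genes with
#'   evidence in at least two species, in `[0, 1]`.
#' @param three_source_rate Fraction of multi-species genes given a
#'   third source.
#' @param n_linkage_intervals,interval_span_bp Linkage interval count
#'   and span.
#' @param n_snps Total marker count.
#' @param snp_density Expected markers placed inside each gene's
#'   flanked region (the rest are uniform over the genome).
#' @param snp_flank_bp Flank defining "inside a gene" for SNP
#'   placement and signal planting (default 10 kb).
#' @param planted_genes `"top-evidence"` (genes ranking at or above
#'   `planted_threshold` under `planted_wsm` given the realized
#'   evidence), an explicit id vector, or `NULL` for a pure null.
#' @param planted_wsm,planted_threshold Matrix / score cutoff defining
#'   `"top-evidence"`.
#' @param planted_effect Beta shape `a` for alternative p-values
#'   (`p ~ Beta(a, 1)`, `a` in `(0, 1]`; `a = 1` is the null).
#' @param defect_rate Fraction of markers given a QC defect (low call
#'   rate, low MAF, or HWE violation, equally likely).
#' @param emit_genotypes Emit per-group genotype counts drawn from a
#'   uniform MAF law so QC statistics can be recomputed from raw
#'   material.
#' @param n_cases,n_controls Sample counts for genotype emission.
#' @param n_sets,set_size_range,enrichment_odds Annotation collection:
#'   set count, size range, and the sampling odds favouring planted
#'   genes in the designated enriched set.
#' @param planted_set_exact If `TRUE` the designated set is exactly
#'   the planted genes.
#' @param seed Integer master seed; every generator derives its own
#'   stream from it, so an identical config reproduces identical
#'   outputs.
#' @return A `crossrank_sim_config` list.
#' @export
sim_config <- function(n_genes = 2000,
                       chrom_layout = c(chr1 = 8e7, chr2 = 6e7,
                                        chr3 = 5e7, chr4 = 4e7),
                       gene_length_law = list(law = "lognormal",
                                              meanlog = log(24000),
                                              sdlog = 1),
                       allow_overlap = TRUE,
                       evidence_counts = c(MuAc = 250, MuPref = 200,
                                           HuAlc = 150, HuAddChip = 100,
                                           Ce = 30, Dr = 50),
                       cross_species_overlap = 0.3,
                       three_source_rate = 0.25,
                       n_linkage_intervals = 3,
                       interval_span_bp = 1.5e7,
                       n_snps = 20000,
                       snp_density = 5,
                       snp_flank_bp = 10000,
                       planted_genes = "top-evidence",
                       planted_wsm = "WSM3",
                       planted_threshold = 2,
                       planted_effect = 0.2,
                       defect_rate = 0.02,
                       emit_genotypes = FALSE,
                       n_cases = 1205,
                       n_controls = 700,
                       n_sets = 40,
                       set_size_range = c(10, 150),
                       enrichment_odds = 8,
                       planted_set_exact = FALSE,
                       seed = 1L) {
  cfg <- as.list(environment())
  if (cfg$n_genes < 0 || cfg$n_snps < 0 || cfg$n_linkage_intervals < 0 ||
      cfg$n_sets < 0 || any(cfg$evidence_counts < 0))
    config_error("all counts must be >= 0")
  if (cfg$cross_species_overlap < 0 || cfg$cross_species_overlap > 1)
    config_error("cross_species_overlap must lie in [0, 1]")
  if (cfg$planted_effect <= 0 || cfg$planted_effect > 1)
    config_error("planted_effect must lie in (0, 1]")
  if (!length(cfg$chrom_layout) || is.null(names(cfg$chrom_layout)))
    config_error("chrom_layout must be a named vector of chromosome lengths")
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "crossrank_sim_config")
}

# Internal: draw gene lengths from the configured law.
draw_gene_lengths <- function(n, law) {
  lens <- switch(law$law,
    lognormal = stats::rlnorm(n, meanlog = law$meanlog, sdlog = law$sdlog),
    uniform = stats::runif(n, min = law$min, max = law$max),
    fixed = rep(law$length, n),
    config_error("unknown gene_length_law '%s'", law$law))
  pmax(1, round(lens))
}

#' Generate a synthetic gene universe
#'
#' Places `n_genes` genes with unique ids and symbols on the
#' configured chromosomes, with lengths drawn from the configured law
#' and 1-based inclusive coordinates. When overlap is disallowed,
#' genes are laid end to end with random gaps; a chromosome whose
#' requested footprint cannot fit raises a sizing error naming it.
#'
#' @param config A [sim_config()].
#' @return Gene table `data.frame` (`gene_id`, `symbol`, `chrom`,
#'   `start`, `end`), sorted by chromosome and start.
#' @export
generate_gene_universe <- function(config) {
  stopifnot(inherits(config, "crossrank_sim_config"))
  empty <- data.frame(gene_id = character(0), symbol = character(0),
                      chrom = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE)
  if (config$n_genes == 0) return(empty)
  with_seed(derive_seed(config$seed, "universe"), {
    n <- config$n_genes
    layout <- config$chrom_layout
    lens <- draw_gene_lengths(n, config$gene_length_law)
    chrom <- sample(names(layout), n, replace = TRUE,
                    prob = layout / sum(layout))
    starts <- integer(n)
    for (cn in names(layout)) {
      idx <- which(chrom == cn)
      if (!length(idx)) next
      L <- layout[[cn]]
      if (any(lens[idx] > L))
        config_error("gene longer than chromosome %s: infeasible layout", cn)
      if (config$allow_overlap) {
        starts[idx] <- vapply(lens[idx], function(l)
          sample.int(L - l + 1L, 1L), 0L)
      } else {
        free <- L - sum(lens[idx])
        if (free < 0)
          config_error(
            "chromosome %s cannot host its %d genes without overlap (short by %.0f bp)",
            cn, length(idx), -free)
        k <- length(idx)
        gaps <- floor(diff(c(0, sort(stats::runif(k)), 1)) * free)
        ord <- sample(k)   # random gene order along the chromosome
        pos <- 1L
        for (j in seq_len(k)) {
          pos <- pos + gaps[j]
          starts[idx[ord[j]]] <- pos
          pos <- pos + lens[idx[ord[j]]]
        }
      }
    }
    df <- data.frame(chrom = chrom, start = as.integer(starts),
                     end = as.integer(starts + lens - 1L),
                     stringsAsFactors = FALSE)
    df <- df[order(df$chrom, df$start), , drop = FALSE]
    df <- data.frame(gene_id = sprintf("G%05d", seq_len(n)),
                     symbol = sprintf("GENE%05d", seq_len(n)),
                     df, stringsAsFactors = FALSE)
    rownames(df) <- NULL
    df
  })
}

#' Generate evidence tracks, ortholog maps and linkage intervals
#'
#' Assigns genes to the six list sources so that the realized fraction
#' of evidence genes with hits in two or more species matches
#' `cross_species_overlap`: a computed number of "multi-species" genes
#' each receive sources in two (or, with probability
#' `three_source_rate`, three) distinct species, and the remaining
#' source slots go to fresh single-source genes. Worm and fly lists
#' are expressed in non-human ids with accompanying ortholog maps so
#' the harmonization path is exercised. Linkage intervals are placed
#' uniformly and linkage membership recorded from gene-body overlap.
#'
#' @param gene_table Gene universe from [generate_gene_universe()].
#' @param config A [sim_config()].
#' @return List: `sets` (the seven membership sets in human ids, for
#'   [build_profiles()]), `worm_ids` / `fly_ids` (native-id lists),
#'   `ortholog_maps` (`Ce`, `Dr`), `intervals`, and `truth`
#'   (`crossrank_truth` with exact memberships and the multi-species
#'   gene set).
#' @export
generate_evidence <- function(gene_table, config) {
  stopifnot(inherits(config, "crossrank_sim_config"))
  counts <- config$evidence_counts
  sources <- names(SOURCE_SPECIES)
  counts <- setNames(as.numeric(counts[sources]), sources)
  counts[is.na(counts)] <- 0
  if (any(counts > nrow(gene_table)))
    config_error("per-source evidence count exceeds the gene universe")
  with_seed(derive_seed(config$seed, "evidence"), {
    f <- config$cross_species_overlap
    p3 <- config$three_source_rate
    total <- sum(counts)
    cap <- counts
    multi <- list()   # per multi gene: character vector of sources
    if (total > 0 && f > 0) {
      n_multi <- if (f >= 1) Inf else
        floor(f * total / (1 + f * (1 + p3)))
      while (length(multi) < n_multi) {
        sp_cap <- tapply(cap, SOURCE_SPECIES[names(cap)], sum)
        sp_cap <- sp_cap[sp_cap > 0]
        if (length(sp_cap) < 2) {
          if (f >= 1) break
          config_error("requested cross-species overlap impossible given per-source counts")
        }
        n_src <- min(2 + (stats::runif(1) < p3), length(sp_cap))
        sp <- if (f >= 1) {
          # full overlap: always drain the dominant species so every
          # leftover slot can still be attached to a multi gene later
          dom <- names(sp_cap)[which.max(sp_cap)]
          others <- setdiff(names(sp_cap), dom)
          picked <- if (length(others) <= n_src - 1) others else
            sample(others, n_src - 1, prob = sp_cap[others])
          c(dom, picked)
        } else sample(names(sp_cap), n_src, prob = sp_cap)
        srcs <- vapply(sp, function(s) {
          pool <- names(cap)[SOURCE_SPECIES[names(cap)] == s & cap > 0]
          if (length(pool) == 1) pool else sample(pool, 1)
        }, "")
        cap[srcs] <- cap[srcs] - 1
        multi[[length(multi) + 1L]] <- srcs
      }
      if (f >= 1 && sum(cap) > 0) {
        # attach leftover single-species slots to existing multi genes
        for (s in names(cap)) {
          while (cap[s] > 0) {
            host <- which(!vapply(multi, function(x) s %in% x, TRUE))
            if (!length(host))
              config_error("requested cross-species overlap impossible given per-source counts")
            i <- host[1]
            multi[[i]] <- c(multi[[i]], s)
            cap[s] <- cap[s] - 1
          }
        }
      }
    }
    singles <- rep(names(cap), times = cap)   # one fresh gene per slot
    n_distinct <- length(multi) + length(singles)
    if (n_distinct > nrow(gene_table))
      config_error("evidence requires %d distinct genes but universe has %d",
                   n_distinct, nrow(gene_table))
    chosen <- if (n_distinct) sample(gene_table$gene_id, n_distinct) else
      character(0)
    memberships <- setNames(vector("list", length(sources)), sources)
    for (s in sources) memberships[[s]] <- character(0)
    multi_ids <- if (length(multi)) chosen[seq_along(multi)] else character(0)
    for (i in seq_along(multi))
      for (s in multi[[i]])
        memberships[[s]] <- c(memberships[[s]], multi_ids[i])
    single_ids <- chosen[setdiff(seq_len(n_distinct), seq_along(multi))]
    for (j in seq_along(singles))
      memberships[[singles[j]]] <- c(memberships[[singles[j]]], single_ids[j])
    memberships <- lapply(memberships, function(x) sort(unique(x)))

    intervals <- generate_linkage_intervals(config)
    hulink <- assign_linkage(gene_table, intervals)

    sets <- c(memberships[c("MuAc", "MuPref", "HuAlc", "HuAddChip")],
              list(HuLink = sort(hulink)),
              memberships[c("Ce", "Dr")])

    prefix_ids <- function(prefix, ids) {
      if (!length(ids)) character(0) else paste0(prefix, ids)
    }
    ce_map <- data.frame(source_id = prefix_ids("cel-", sets$Ce),
                         human_gene_id = sets$Ce, stringsAsFactors = FALSE)
    dr_map <- data.frame(source_id = prefix_ids("dmel-", sets$Dr),
                         human_gene_id = sets$Dr, stringsAsFactors = FALSE)

    truth <- structure(list(
      memberships = sets,
      multi_species = sort(multi_ids),
      planted = character(0),
      snp_labels = NULL), class = "crossrank_truth")

    list(sets = sets,
         worm_ids = ce_map$source_id, fly_ids = dr_map$source_id,
         ortholog_maps = list(Ce = ce_map, Dr = dr_map),
         intervals = intervals,
         truth = truth)
  })
}

# Internal: place linkage intervals uniformly over chromosomes that can
# host the configured span.
generate_linkage_intervals <- function(config) {
  n <- config$n_linkage_intervals
  span <- config$interval_span_bp
  if (n == 0)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), label = character(0),
                      stringsAsFactors = FALSE))
  layout <- config$chrom_layout[config$chrom_layout >= span]
  if (!length(layout))
    config_error("no chromosome can host a linkage interval of %.0f bp", span)
  chrom <- sample(names(layout), n, replace = TRUE,
                  prob = layout / sum(layout))
  start <- vapply(chrom, function(cn)
    sample.int(as.integer(layout[[cn]] - span + 1), 1L), 0L)
  data.frame(chrom = chrom, start = start,
             end = as.integer(start + span - 1),
             label = sprintf("LNK%02d", seq_len(n)),
             stringsAsFactors = FALSE)
}

# Internal: resolve the planted gene set for a config.
resolve_planted <- function(gene_table, truth, config) {
  pg <- config$planted_genes
  if (is.null(pg) || !length(pg)) return(character(0))
  if (identical(pg, "top-evidence")) {
    profiles <- build_profiles(gene_table, truth$memberships)
    ranked <- rank_genes(profiles, wsm_preset(config$planted_wsm))
    return(select_top(ranked, config$planted_threshold, "ge")$gene_id)
  }
  if (!all(pg %in% gene_table$gene_id))
    config_error("planted gene id(s) absent from the gene universe")
  pg
}

#' Generate a synthetic GWAS marker table
#'
#' Markers are placed both inside gene regions (gene +/- flank,
#' `snp_density` expected markers per gene) and uniformly over the
#' genome. Null markers receive `p ~ Uniform(0, 1)`; markers inside a
#' planted gene's flanked region receive `p ~ Beta(a, 1)` with
#' `a = planted_effect`. A `defect_rate` fraction of markers is given
#' a call-rate, MAF, or HWE defect so QC filters have work to do;
#' genotype counts drawn under a uniform MAF law are emitted when
#' `emit_genotypes` is set.
#'
#' @param gene_table Gene universe.
#' @param truth `crossrank_truth` from [generate_evidence()] (used to
#'   resolve `"top-evidence"` planting); may be `NULL` when planting
#'   explicit ids or nothing.
#' @param config A [sim_config()].
#' @return List: `snps` (marker `data.frame` with `snp_id`, `chrom`,
#'   `pos`, `p`, `call_rate`, `maf`, `hwe_p` and optional genotype
#'   counts) and `truth` (input truth with `planted` and per-SNP
#'   `snp_labels` filled in).
#' @export
generate_gwas <- function(gene_table, truth, config) {
  stopifnot(inherits(config, "crossrank_sim_config"))
  layout <- config$chrom_layout
  if (!length(layout)) config_error("zero chromosomes configured")
  planted <- resolve_planted(gene_table, truth, config)
  with_seed(derive_seed(config$seed, "gwas"), {
    n <- config$n_snps
    n_genic <- if (nrow(gene_table))
      min(n, round(config$snp_density * nrow(gene_table))) else 0
    n_bg <- n - n_genic
    flank <- config$snp_flank_bp
    chrom <- character(0); pos <- integer(0)
    if (n_genic > 0) {
      gi <- sample.int(nrow(gene_table), n_genic, replace = TRUE)
      lo <- pmax(1, gene_table$start[gi] - flank)
      hi <- pmin(layout[gene_table$chrom[gi]], gene_table$end[gi] + flank)
      chrom <- c(chrom, gene_table$chrom[gi])
      pos <- c(pos, as.integer(floor(stats::runif(n_genic, lo, hi + 1))))
    }
    if (n_bg > 0) {
      bc <- sample(names(layout), n_bg, replace = TRUE,
                   prob = layout / sum(layout))
      chrom <- c(chrom, bc)
      pos <- c(pos, as.integer(floor(stats::runif(n_bg, 1, layout[bc] + 1))))
    }
    ord <- order(chrom, pos)
    snps <- data.frame(snp_id = sprintf("rs%06d", seq_len(n)),
                       chrom = chrom[ord], pos = pos[ord],
                       stringsAsFactors = FALSE)
    # alternative labels: inside a planted gene's flanked window
    is_alt <- rep(FALSE, n)
    if (length(planted) && n > 0) {
      pg <- gene_table[gene_table$gene_id %in% planted, , drop = FALSE]
      pm <- map_snps_to_genes(snps, pg, flank_bp = flank)
      is_alt <- snps$snp_id %in% pm$map$snp_id
    }
    p <- stats::runif(n)
    if (any(is_alt))
      p[is_alt] <- stats::rbeta(sum(is_alt), config$planted_effect, 1)
    p <- pmax(p, .Machine$double.xmin)   # keep p in (0, 1]
    snps$p <- p
    # QC statistics with a defect fraction
    snps$call_rate <- stats::runif(n, 0.97, 1)
    snps$maf <- stats::runif(n, 0.05, 0.5)
    snps$hwe_p <- stats::runif(n)
    n_def <- round(config$defect_rate * n)
    if (n_def > 0) {
      di <- sample.int(n, n_def)
      kind <- sample(c("call", "maf", "hwe"), n_def, replace = TRUE)
      snps$call_rate[di[kind == "call"]] <-
        stats::runif(sum(kind == "call"), 0.85, 0.949)
      snps$maf[di[kind == "maf"]] <-
        stats::runif(sum(kind == "maf"), 0.0005, 0.009)
      snps$hwe_p[di[kind == "hwe"]] <-
        10^-stats::runif(sum(kind == "hwe"), 6.5, 12)
    }
    if (config$emit_genotypes) {
      geno <- emit_genotype_counts(snps, config)
      snps <- cbind(snps, geno)
    }
    truth2 <- if (is.null(truth))
      structure(list(memberships = NULL, multi_species = character(0),
                     planted = planted, snp_labels = NULL),
                class = "crossrank_truth") else truth
    truth2$planted <- planted
    truth2$snp_labels <- data.frame(
      snp_id = snps$snp_id,
      status = ifelse(snps$snp_id %in% snps$snp_id[is_alt], "alt", "null"),
      stringsAsFactors = FALSE)
    list(snps = snps, truth = truth2)
  })
}

# Internal: per-group genotype counts consistent with each marker's MAF
# and call rate (Hardy-Weinberg proportions in both groups; the
# association p-value column is generated separately and is not implied
# by these counts).
emit_genotype_counts <- function(snps, config) {
  n <- nrow(snps)
  draw <- function(n_samples) {
    t(vapply(seq_len(n), function(i) {
      m <- round(n_samples * snps$call_rate[i])
      q <- snps$maf[i]
      as.integer(stats::rmultinom(1, m, c((1 - q)^2, 2 * q * (1 - q), q^2)))
    }, integer(3)))
  }
  cs <- draw(config$n_cases); ct <- draw(config$n_controls)
  data.frame(case_AA = cs[, 1], case_Aa = cs[, 2], case_aa = cs[, 3],
             ctrl_AA = ct[, 1], ctrl_Aa = ct[, 2], ctrl_aa = ct[, 3])
}

#' Generate a GMT annotation collection
#'
#' Writes `n_sets` random gene sets; one designated set is enriched
#' for the planted genes with sampling odds `enrichment_odds` (or is
#' exactly the planted set when `planted_set_exact`).
#'
#' @param gene_table Gene universe.
#' @param truth `crossrank_truth` carrying the planted gene ids.
#' @param config A [sim_config()].
#' @return Named list of gene sets with attribute `"designated"` (the
#'   enriched set's name, or `NA` if nothing is planted).
#' @export
generate_annotations <- function(gene_table, truth, config) {
  stopifnot(inherits(config, "crossrank_sim_config"))
  if (config$n_sets < 1) config_error("n_sets must be >= 1")
  universe <- gene_table$gene_id
  rng <- pmin(config$set_size_range, length(universe))
  if (any(config$set_size_range > length(universe)))
    config_error("set size range exceeds the gene universe")
  planted <- if (!is.null(truth)) truth$planted else character(0)
  with_seed(derive_seed(config$seed, "annotations"), {
    sets <- lapply(seq_len(config$n_sets), function(j) {
      s <- sample(seq(rng[1], rng[2]), 1)
      sort(sample(universe, s))
    })
    names(sets) <- sprintf("SET%03d", seq_len(config$n_sets))
    designated <- NA_character_
    if (length(planted)) {
      designated <- names(sets)[1]
      if (config$planted_set_exact) {
        sets[[1]] <- sort(planted)
      } else {
        s <- max(length(sets[[1]]), length(planted))
        w <- ifelse(universe %in% planted, config$enrichment_odds, 1)
        sets[[1]] <- sort(sample(universe, min(s, length(universe)), prob = w))
      }
    }
    attr(sets, "designated") <- designated
    sets
  })
}

#' Generate a complete synthetic study
#'
#' Runs the four generators in order and, when `dir` is given, writes
#' every artifact in its on-disk format: gene universe TSV, one
#' evidence list per source (worm and fly in native ids), ortholog map
#' TSVs, linkage BED, SNP TSV, GMT collection, and a ground-truth JSON.
#' Identical configs (including the seed) produce byte-identical
#' files.
#'
#' @param config A [sim_config()].
#' @param dir Optional output directory (created if needed).
#' @return A `crossrank_study` list: `gene_table`, `evidence`
#'   (see [generate_evidence()]), `snps`, `sets`, `truth`, `config`,
#'   and `paths` when files were written.
#' @export
simulate_study <- function(config = sim_config(), dir = NULL) {
  gene_table <- generate_gene_universe(config)
  evidence <- generate_evidence(gene_table, config)
  gwas <- generate_gwas(gene_table, evidence$truth, config)
  sets <- generate_annotations(gene_table, gwas$truth, config)
  study <- structure(list(gene_table = gene_table, evidence = evidence,
                          snps = gwas$snps, sets = sets,
                          truth = gwas$truth, config = config,
                          paths = NULL), class = "crossrank_study")
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    pth <- function(f) file.path(dir, f)
    paths <- list(genes = pth("genes.tsv"), snps = pth("snps.tsv"),
                  linkage = pth("linkage.bed"), gmt = pth("sets.gmt"),
                  truth = pth("truth.json"))
    write_gene_table(gene_table, paths$genes)
    for (s in c("MuAc", "MuPref", "HuAlc", "HuAddChip")) {
      paths[[s]] <- pth(sprintf("evidence_%s.txt", s))
      write_evidence_list(evidence$sets[[s]], paths[[s]],
                          comment = sprintf("synthetic %s evidence list", s))
    }
    paths$Ce <- pth("evidence_Ce.txt")
    write_evidence_list(evidence$worm_ids, paths$Ce,
                        comment = "synthetic worm evidence list (native ids)")
    paths$Dr <- pth("evidence_Dr.txt")
    write_evidence_list(evidence$fly_ids, paths$Dr,
                        comment = "synthetic fly evidence list (native ids)")
    paths$Ce_map <- pth("orthologs_Ce.tsv")
    write_ortholog_map(evidence$ortholog_maps$Ce, paths$Ce_map)
    paths$Dr_map <- pth("orthologs_Dr.tsv")
    write_ortholog_map(evidence$ortholog_maps$Dr, paths$Dr_map)
    write_linkage_bed(evidence$intervals, paths$linkage)
    write_snp_table(gwas$snps, paths$snps)
    write_gmt(sets, paths$gmt)
    jsonlite::write_json(
      list(planted = study$truth$planted,
           multi_species = study$truth$multi_species,
           memberships = study$truth$memberships,
           designated_set = attr(sets, "designated")),
      paths$truth, auto_unbox = TRUE, pretty = TRUE)
    study$paths <- paths
  }
  study
}
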