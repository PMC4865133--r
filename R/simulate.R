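#' Build a simulation configuration
#'
#' Collects every knob of the synthetic-data generator in one validated
#' object: genome geometry, cytosine landscape, coverage, context- and
#' feature-kind-specific baseline methylation, expression and small-RNA
#' models, and the planted effects (hypo-DMRs, up-regulated features,
#' siRNA dependence labels). Every generator is a pure function of
#' (config, genotype): the same seed yields byte-identical outputs.
#'
#' The read model is per-site binomial: coverage ~ Poisson(
#' `coverage_mean`), methylated reads ~ Binomial(coverage, level), with
#' level = baseline(kind, context) plus any planted delta, clamped to
#' [0, 1]. An optional bisulfite non-conversion rate (default 0) adds
#' `(1 - level) * rate` to the observed level. Contexts are assigned to
#' sites by configured proportions rather than derived from simulated
#' sequence, so no reference FASTA is needed.
#'
#' Expression counts use a latent Gamma-Poisson construction: each
#' feature draws one latent mean (Gamma with the configured dispersion
#' around its kind's base mean), shared across genotypes, and each
#' genotype draws Poisson counts around that latent mean times any
#' planted fold. Marginally the counts are negative binomial with the
#' configured dispersion; between genotypes the null variation is pure
#' counting noise, which is the regime an exact test on counts assumes.
#'
#' @param seed Integer seed; all stage seeds are derived from it.
#' @param n_chromosomes,chromosome_length Genome geometry (default 2 x
#'   150 kb).
#' @param site_density Cytosines per bp, both strands together
#'   (default 0.15).
#' @param context_probs Context proportions for CG/CHG/CHH (defaults
#'   0.17/0.17/0.66, the approximate genomic proportions in
#'   Arabidopsis).
#' @param coverage_mean Poisson mean of per-site read coverage
#'   (default 20).
#' @param baseline 3x3 matrix of methylation levels, rows gene/TE/other,
#'   columns CG/CHG/CHH.
#' @param non_conversion_rate Bisulfite non-conversion rate (default 0).
#' @param n_genes,n_tes,gene_length,te_length Annotation geometry.
#' @param genotypes Methylome/expression genotype labels; the first is
#'   the wild type.
#' @param sirna_genotypes Small-RNA genotype labels.
#' @param base_mean_gene,base_mean_te,dispersion Expression model.
#' @param sirna_lib_totals Named small-RNA library totals.
#' @param sirna_background_mean Expected 24-nt count for unlabeled
#'   features (default 2).
#' @param planted_dmrs,planted_de,sirna_truth Planted-effect tables;
#'   usually filled by a scenario builder such as
#'   [te_silencing_scenario()].
#' @param annotation Optional pre-built annotation (cached by scenario
#'   builders so planted intervals and features stay consistent).
#' @return An object of class `"rddmr_config"`.
#' @export
simulation_config <- function(seed = 1L,
                              n_chromosomes = 2L,
                              chromosome_length = 150000L,
                              site_density = 0.15,
                              context_probs = c(CG = 0.17, CHG = 0.17,
                                                CHH = 0.66),
                              coverage_mean = 20,
                              baseline = rbind(
                                gene = c(CG = 0.20, CHG = 0.03, CHH = 0.02),
                                TE = c(CG = 0.85, CHG = 0.45, CHH = 0.30),
                                other = c(CG = 0.05, CHG = 0.03, CHH = 0.02)),
                              non_conversion_rate = 0,
                              n_genes = 80L, n_tes = 80L,
                              gene_length = 1500L, te_length = 400L,
                              genotypes = c("WT", "suvh29", "morc6"),
                              sirna_genotypes = c("WT", "nrpd1", "nrpe1"),
                              base_mean_gene = 100, base_mean_te = 30,
                              dispersion = 0.1,
                              sirna_lib_totals = c(WT = 8e6, nrpd1 = 1.2e7,
                                                   nrpe1 = 9e6),
                              sirna_background_mean = 2,
                              planted_dmrs = NULL, planted_de = NULL,
                              sirna_truth = NULL, annotation = NULL) {
  if (any(context_probs < 0) || abs(sum(context_probs) - 1) > 1e-8) {
    stop_param("context_probs must be non-negative and sum to 1")
  }
  if (any(baseline < 0 | baseline > 1)) {
    stop_param("baseline methylation levels must lie in [0, 1]")
  }
  if (coverage_mean < 0 || site_density < 0 || site_density > 1) {
    stop_param("coverage_mean must be >= 0 and site_density in [0, 1]")
  }
  chroms <- stats::setNames(rep(as.integer(chromosome_length),
                                n_chromosomes),
                            paste0("Chr", seq_len(n_chromosomes)))
  cfg <- list(seed = as.integer(seed), chromosomes = chroms,
              site_density = site_density, context_probs = context_probs,
              coverage_mean = coverage_mean, baseline = baseline,
              non_conversion_rate = non_conversion_rate,
              n_genes = as.integer(n_genes), n_tes = as.integer(n_tes),
              gene_length = as.integer(gene_length),
              te_length = as.integer(te_length),
              genotypes = genotypes, sirna_genotypes = sirna_genotypes,
              base_mean_gene = base_mean_gene, base_mean_te = base_mean_te,
              dispersion = dispersion,
              sirna_lib_totals = sirna_lib_totals,
              sirna_background_mean = sirna_background_mean,
              planted_dmrs = planted_dmrs, planted_de = planted_de,
              sirna_truth = sirna_truth, annotation = annotation)
  class(cfg) <- "rddmr_config"
  cfg
}

#' Simulate a gene/TE annotation
#'
#' Places the configured numbers of genes and TEs, non-overlapping and
#' in random order, along each chromosome with random inter-feature
#' gaps; the rest of the chromosome is uncharacterized ("other") space.
#' Deterministic under the config seed. If the config carries a cached
#' annotation (scenario builders do this so planted intervals stay
#' consistent), that annotation is returned unchanged.
#'
#' @param config An [simulation_config()] object.
#' @return Feature data frame as from [read_features()].
#' @export
simulate_annotation <- function(config) {
  if (!is.null(config$annotation)) return(config$annotation)
  total <- config$n_genes + config$n_tes
  if (total == 0L) {
    return(data.frame(feature_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), kind = character(),
                      stringsAsFactors = FALSE))
  }
  nchrom <- length(config$chromosomes)
  kinds <- rep(c("gene", "TE"), c(config$n_genes, config$n_tes))
  chrom_of <- rep(seq_len(nchrom), length.out = total)
  with_seed(derive_seed(config$seed, "annotation"), {
    rows <- vector("list", nchrom)
    counters <- c(gene = 0L, TE = 0L)
    for (ci in seq_len(nchrom)) {
      k <- sample(kinds[chrom_of == ci])
      len <- ifelse(k == "gene", config$gene_length, config$te_length)
      gap_total <- config$chromosomes[ci] - sum(len)
      if (gap_total < 0) {
        stop_param("features exceed chromosome length on %s",
                   names(config$chromosomes)[ci])
      }
      gaps <- as.vector(stats::rmultinom(1, gap_total,
                                         rep(1, length(k) + 1L)))
      start <- cumsum(gaps[-length(gaps)] + c(0L, len[-length(len)])) + 1L
      ids <- character(length(k))
      for (i in seq_along(k)) {
        counters[k[i]] <- counters[k[i]] + 1L
        ids[i] <- sprintf("%s_%03d", ifelse(k[i] == "gene", "gene", "TE"),
                          counters[k[i]])
      }
      rows[[ci]] <- data.frame(
        feature_id = ids, chrom = names(config$chromosomes)[ci],
        start = as.integer(start), end = as.integer(start + len - 1L),
        strand = sample(c("+", "-"), length(k), replace = TRUE),
        kind = k, stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })
}

#' Simulate a per-cytosine methylation report for one genotype
#'
#' The cytosine landscape (positions, strands, contexts) is drawn once
#' from the config seed and is identical across genotypes; coverage and
#' methylated-read draws use a genotype-specific derived seed. Sites in
#' a planted DMR affecting the genotype have the configured per-context
#' deltas added to their generating level (clamped to \[0, 1\]). Sites
#' that draw zero coverage are not reported.
#'
#' @param config An [simulation_config()] object.
#' @param annotation Annotation data frame (defaults to
#'   [simulate_annotation()] on the config).
#' @param genotype A label from `config$genotypes`.
#' @return Cytosine report data frame (see [read_cytosine_report()]).
#' @export
simulate_methylome <- function(config, annotation = NULL, genotype) {
  if (!genotype %in% config$genotypes) {
    stop_param("genotype '%s' is not listed in the config", genotype)
  }
  ann <- annotation %||% simulate_annotation(config)
  sites <- with_seed(derive_seed(config$seed, "sites"), {
    out <- lapply(seq_along(config$chromosomes), function(ci) {
      len <- config$chromosomes[ci]
      n <- round(len * config$site_density)
      if (n == 0L) return(NULL)
      data.frame(
        chrom = names(config$chromosomes)[ci],
        pos = sort(sample.int(len, n)),
        strand = sample(c("+", "-"), n, replace = TRUE),
        context = sample(CONTEXTS, n, replace = TRUE,
                         prob = config$context_probs),
        stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
  if (is.null(sites) || nrow(sites) == 0L) {
    return(data.frame(chrom = character(), pos = integer(),
                      strand = character(), context = character(),
                      count_meth = integer(), count_unmeth = integer(),
                      stringsAsFactors = FALSE))
  }
  kind <- rep("other", nrow(sites))
  if (nrow(ann) > 0L) {
    gs <- GenomicRanges::GRanges(sites$chrom,
                                 IRanges::IRanges(sites$pos, width = 1L))
    h <- GenomicRanges::findOverlaps(gs, features_granges(ann),
                                     ignore.strand = TRUE,
                                     select = "first")
    kind[!is.na(h)] <- ann$kind[h[!is.na(h)]]
  }
  level <- config$baseline[cbind(kind, sites$context)]
  pd <- config$planted_dmrs
  if (!is.null(pd) && nrow(pd) > 0L) {
    for (i in seq_len(nrow(pd))) {
      affected <- strsplit(pd$genotypes[i], ",", fixed = TRUE)[[1]]
      if (!genotype %in% trimws(affected)) next
      in_dmr <- sites$chrom == pd$chrom[i] & sites$pos >= pd$start[i] &
        sites$pos <= pd$end[i]
      if (!any(in_dmr)) next
      delta <- c(CG = pd$delta_CG[i], CHG = pd$delta_CHG[i],
                 CHH = pd$delta_CHH[i])[sites$context[in_dmr]]
      level[in_dmr] <- pmin(1, pmax(0, level[in_dmr] + delta))
    }
  }
  level_obs <- level + (1 - level) * config$non_conversion_rate
  with_seed(derive_seed(config$seed, paste0("meth:", genotype)), {
    cov <- stats::rpois(nrow(sites), config$coverage_mean)
    m <- stats::rbinom(nrow(sites), cov, level_obs)
    keep <- cov > 0L
    data.frame(chrom = sites$chrom[keep], pos = sites$pos[keep],
               strand = sites$strand[keep], context = sites$context[keep],
               count_meth = m[keep], count_unmeth = cov[keep] - m[keep],
               stringsAsFactors = FALSE)
  })
}

#' Simulate an expression count table for one genotype
#'
#' Latent Gamma-Poisson draw (see [simulation_config()]): per-feature
#' latent means are shared across genotypes; planted folds multiply the
#' latent mean in the affected genotype.
#'
#' @inheritParams simulate_methylome
#' @return Data frame with `feature_id`, `kind` and `count`.
#' @export
simulate_expression <- function(config, annotation = NULL, genotype) {
  if (!genotype %in% config$genotypes) {
    stop_param("genotype '%s' is not listed in the config", genotype)
  }
  ann <- annotation %||% simulate_annotation(config)
  if (nrow(ann) == 0L) {
    return(data.frame(feature_id = character(), kind = character(),
                      count = integer(), stringsAsFactors = FALSE))
  }
  base <- ifelse(ann$kind == "gene", config$base_mean_gene,
                 config$base_mean_te)
  lat <- with_seed(derive_seed(config$seed, "expr_latent"), {
    if (config$dispersion > 0) {
      stats::rgamma(nrow(ann), shape = 1 / config$dispersion,
                    scale = base * config$dispersion)
    } else {
      base
    }
  })
  fold <- rep(1, nrow(ann))
  pde <- config$planted_de
  if (!is.null(pde) && nrow(pde) > 0L) {
    rows <- pde[pde$genotype == genotype, , drop = FALSE]
    idx <- match(rows$feature_id, ann$feature_id)
    fold[idx[!is.na(idx)]] <- rows$fold[!is.na(idx)]
  }
  counts <- with_seed(derive_seed(config$seed, paste0("expr:", genotype)),
                      stats::rpois(nrow(ann), lat * fold))
  data.frame(feature_id = ann$feature_id, kind = ann$kind,
             count = counts, stringsAsFactors = FALSE)
}

#' Simulate a length-stratified small-RNA count table for one genotype
#'
#' 24-nt counts are Poisson around a per-feature wild-type mean (from
#' the planted dependence table; a small background mean for unlabeled
#' features) scaled by the genotype's planted dependence factor and by
#' the genotype's library size relative to the RPTM scale. Minor
#' 21-23-nt background strata are included.
#'
#' @inheritParams simulate_methylome
#' @param genotype A label from `config$sirna_genotypes`.
#' @return Long data frame with `feature_id`, `genotype`, `read_length`
#'   and `count`.
#' @export
simulate_sirna <- function(config, annotation = NULL, genotype) {
  if (!genotype %in% config$sirna_genotypes) {
    stop_param("genotype '%s' is not a small-RNA genotype", genotype)
  }
  ann <- annotation %||% simulate_annotation(config)
  wt_mean <- rep(config$sirna_background_mean, nrow(ann))
  scale <- rep(1, nrow(ann))
  truth <- config$sirna_truth
  if (!is.null(truth) && nrow(truth) > 0L) {
    idx <- match(truth$feature_id, ann$feature_id)
    wt_mean[idx[!is.na(idx)]] <- truth$wt_mean[!is.na(idx)]
    scol <- paste0("scale_", genotype)
    if (scol %in% names(truth)) {
      scale[idx[!is.na(idx)]] <- truth[[scol]][!is.na(idx)]
    }
  }
  lib_factor <- config$sirna_lib_totals[[genotype]] / 1e7
  with_seed(derive_seed(config$seed, paste0("sirna:", genotype)), {
    c24 <- stats::rpois(nrow(ann), wt_mean * scale * lib_factor)
    minor <- lapply(21:23, function(l) {
      data.frame(feature_id = ann$feature_id, genotype = genotype,
                 read_length = l,
                 count = stats::rpois(nrow(ann), 1 * lib_factor),
                 stringsAsFactors = FALSE)
    })
    rbind(do.call(rbind, minor),
          data.frame(feature_id = ann$feature_id, genotype = genotype,
                     read_length = 24L, count = c24,
                     stringsAsFactors = FALSE))
  })
}

#' The default two-mutant TE-silencing scenario
#'
#' Builds the scenario the package's recovery tests and pipeline default
#' to, mirroring the qualitative structure of a two-mutant methylome /
#' transcriptome study at reduced scale: on a 2 x 150-kb genome with 80
#' genes and 80 TEs it plants
#'
#' * 60 hypo-DMRs of 300 bp inside distinct TEs in the `suvh29`
#'   genotype, with per-context deltas CG -0.10, CHG -0.15, CHH -0.30,
#'   of which the first 15 are shared with `morc6` (the Class I
#'   analogue);
#' * 30 up-regulated TEs (fold 4) in each mutant, 12 of them common;
#'   the `morc6` up-set is chosen among TEs with no planted `morc6`
#'   methylation change, reconstructing silencing release without
#'   methylation loss;
#' * Pol IV-dependent 24-nt siRNAs at all 60 DMR TEs (nrpd1 scale
#'   0.02); half of them also Pol V-dependent (nrpe1 scale 0.02), half
#'   Pol V-independent (nrpe1 scale 1).
#'
#' @param seed Integer seed.
#' @return An `"rddmr_config"` with annotation and planted-effect tables
#'   filled in.
#' @export
te_silencing_scenario <- function(seed = 1L) {
  cfg <- simulation_config(seed = seed)
  ann <- simulate_annotation(cfg)
  tes <- ann[ann$kind == "TE", , drop = FALSE]
  tes <- tes[order(tes$feature_id), , drop = FALSE]
  n_dmr <- 60L
  host <- tes[seq_len(n_dmr), , drop = FALSE]
  dmr_width <- 300L
  offset <- with_seed(derive_seed(seed, "plant_dmrs"),
                      sample.int(cfg$te_length - dmr_width + 1L, n_dmr,
                                 replace = TRUE) - 1L)
  cfg$planted_dmrs <- data.frame(
    dmr_id = sprintf("dmr_%03d", seq_len(n_dmr)),
    chrom = host$chrom,
    start = host$start + offset,
    end = host$start + offset + dmr_width - 1L,
    feature_id = host$feature_id,
    genotypes = c(rep("suvh29,morc6", 15L), rep("suvh29", n_dmr - 15L)),
    direction = "hypo",
    delta_CG = -0.10, delta_CHG = -0.15, delta_CHH = -0.30,
    stringsAsFactors = FALSE)
  up_suvh29 <- host$feature_id[13:42]
  up_morc6 <- host$feature_id[31:60]   # no planted morc6 methylation delta
  cfg$planted_de <- data.frame(
    feature_id = c(up_suvh29, up_morc6),
    genotype = rep(c("suvh29", "morc6"), c(length(up_suvh29),
                                           length(up_morc6))),
    fold = 4, stringsAsFactors = FALSE)
  wt_mean <- with_seed(derive_seed(seed, "sirna_means"),
                       stats::runif(n_dmr, 100, 400))
  cfg$sirna_truth <- data.frame(
    feature_id = host$feature_id,
    wt_mean = wt_mean,
    scale_nrpd1 = 0.02,
    scale_nrpe1 = rep(c(0.02, 1), each = n_dmr / 2L),
    label = rep(c("polIV_dependent_polV_dependent",
                  "polIV_dependent_polV_independent"), each = n_dmr / 2L),
    stringsAsFactors = FALSE)
  cfg$annotation <- ann
  cfg
}

#' A null scenario with no planted differences
#'
#' Same genome, annotation geometry and coverage model as the default
#' scenario but two genotypes generated from identical methylation
#' levels — the calibration input for the windowed Fisher test. The
#' default geometry yields slightly over 10,000 testable 50-bp windows.
#'
#' @param seed Integer seed.
#' @param chromosome_length Per-chromosome length (default 255 kb).
#' @return An `"rddmr_config"`.
#' @export
null_scenario <- function(seed = 1L, chromosome_length = 255000L) {
  simulation_config(seed = seed, chromosome_length = chromosome_length,
                    genotypes = c("WT", "mutant"))
}

#' A differential-expression benchmark scenario
#'
#' 1,000 features (500 genes, 500 TEs) with 4-fold up-regulation
#' planted at 50 TEs in a single mutant; all other features are null.
#' Used to measure sensitivity and false-positive rate of the
#' fold-change + Fisher rule under the latent Gamma-Poisson count model
#' at dispersion 0.1.
#'
#' @param seed Integer seed.
#' @return An `"rddmr_config"`.
#' @export
de_benchmark_scenario <- function(seed = 1L) {
  cfg <- simulation_config(seed = seed, n_chromosomes = 2L,
                           chromosome_length = 600000L,
                           n_genes = 500L, n_tes = 500L,
                           genotypes = c("WT", "mutant"))
  ann <- simulate_annotation(cfg)
  tes <- sort(ann$feature_id[ann$kind == "TE"])
  cfg$planted_de <- data.frame(feature_id = tes[seq_len(50L)],
                               genotype = "mutant", fold = 4,
                               stringsAsFactors = FALSE)
  cfg$annotation <- ann
  cfg
}

#' Materialize a simulated dataset on disk
#'
#' Writes everything a pipeline run consumes: one cytosine report per
#' genotype, the annotation as GFF3, the expression count table, the
#' length-stratified small-RNA counts with library totals, the planted
#' ground truth, and a JSON snapshot of the configuration.
#'
#' @param config An `"rddmr_config"`.
#' @param outdir Output directory (created if needed).
#' @return Named list of written paths, invisibly.
#' @export
simulate_dataset <- function(config, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  ann <- simulate_annotation(config)
  paths <- list(annotation = file.path(outdir, "annotation.gff3"))
  write_features_gff3(ann, paths$annotation)

  for (g in config$genotypes) {
    p <- file.path(outdir, paste0("report_", g, ".tsv"))
    write_cytosine_report(simulate_methylome(config, ann, g), p)
    paths[[paste0("report_", g)]] <- p
  }

  expr <- NULL
  for (g in config$genotypes) {
    tab <- simulate_expression(config, ann, g)
    names(tab)[names(tab) == "count"] <- g
    expr <- if (is.null(expr)) tab else
      merge(expr, tab, by = c("feature_id", "kind"), sort = FALSE)
  }
  expr <- expr[order(expr$feature_id), , drop = FALSE]
  paths$expression <- file.path(outdir, "expression_counts.tsv")
  utils::write.table(expr, paths$expression, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  sirna <- do.call(rbind, lapply(config$sirna_genotypes, function(g) {
    simulate_sirna(config, ann, g)
  }))
  paths$sirna <- file.path(outdir, "sirna_counts.tsv")
  utils::write.table(sirna, paths$sirna, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  libs <- data.frame(genotype = config$sirna_genotypes,
                     library_total = unname(
                       config$sirna_lib_totals[config$sirna_genotypes]))
  paths$sirna_libs <- file.path(outdir, "sirna_libs.tsv")
  utils::write.table(libs, paths$sirna_libs, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  truth <- ground_truth(config)
  for (nm in names(truth)) {
    p <- file.path(outdir, paste0("ground_truth_", nm, ".tsv"))
    utils::write.table(truth[[nm]], p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths[[paste0("truth_", nm)]] <- p
  }

  paths$config <- file.path(outdir, "config.json")
  snap <- unclass(config)
  snap$annotation <- NULL
  snap$baseline <- as.data.frame(snap$baseline)
  jsonlite::write_json(snap, paths$config, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}

#' Planted ground truth of a configuration
#'
#' @param config An `"rddmr_config"`.
#' @return List with data frames `dmrs`, `de` and `sirna` (empty data
#'   frames when nothing is planted).
#' @export
ground_truth <- function(config) {
  list(
    dmrs = config$planted_dmrs %||%
      data.frame(dmr_id = character(), chrom = character(),
                 start = integer(), end = integer(),
                 feature_id = character(), genotypes = character(),
                 direction = character(), delta_CG = numeric(),
                 delta_CHG = numeric(), delta_CHH = numeric(),
                 stringsAsFactors = FALSE),
    de = config$planted_de %||%
      data.frame(feature_id = character(), genotype = character(),
                 fold = numeric(), stringsAsFactors = FALSE),
    sirna = config$sirna_truth %||%
      data.frame(feature_id = character(), wt_mean = numeric(),
                 scale_nrpd1 = numeric(), scale_nrpe1 = numeric(),
                 label = character(), stringsAsFactors = FALSE))
}
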