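#' Run the full silencing-classification pipeline
#'
#' Executes the whole analysis chain on one dataset: (optionally)
#' simulate inputs, call DMRs for every mutant against the wild type,
#' partition and compare the two mutant DMR sets (shared "Class I"
#' versus specific "Class II"), classify DMRs by genomic location, call
#' differential expression and partition common/specific up-regulated
#' TEs and genes, compute feature and promoter methylation with class
#' filters and deltas against the wild type, and profile 24-nt siRNA
#' dependence. Every stage reads its inputs from files and writes its
#' outputs to files, so any stage is independently re-runnable; a JSON
#' manifest records the configuration, parameters, checksums and
#' runtimes. On a stage failure the run aborts with the stage name, and
#' files of the failed stage keep a `.partial` suffix.
#'
#' All thresholds live in `params` and are echoed into the manifest;
#' the defaults are the published procedure's values (50-bp windows,
#' 5x coverage, 10% difference, p < 0.01, 50-bp merge gap, >50-bp
#' overlap, fold-change > 2, 1-kb promoters, RPTM scale 1e7,
#' dependence cutoff 0.5).
#'
#' @param config An `"rddmr_config"` (see [te_silencing_scenario()]).
#' @param outdir Output directory.
#' @param simulate Generate inputs under `outdir/sim` (default `TRUE`).
#'   With `simulate = FALSE`, `input_dir` must contain files laid out as
#'   written by [simulate_dataset()].
#' @param input_dir Directory of pre-existing inputs.
#' @param params Named list overriding analysis thresholds; see
#'   Details.
#' @return Invisibly, a list with `outdir`, per-stage output `paths`,
#'   the `summary` data frame and the `manifest`.
#' @export
run_full_pipeline <- function(config, outdir, simulate = TRUE,
                              input_dir = NULL, params = list()) {
  p0 <- list(window_size = 50L, min_coverage = 5L, min_sites = 1L,
             context = "total", delta_min = 0.10, alpha = 0.01,
             max_gap = 50L, min_overlap = 50L, fc_min = 2,
             de_alpha = 0.01, de_pseudocount = 0.5, promoter_len = 1000L,
             te_threshold = 0.20, promoter_threshold = 0.05,
             dependence_cutoff = 0.5, sirna_pseudocount = 1,
             min_wt_rptm = 5)
  unknown <- setdiff(names(params), names(p0))
  if (length(unknown)) {
    stop_param("unknown parameter(s): %s", paste(unknown, collapse = ", "))
  }
  p0[names(params)] <- params
  params <- p0
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  wt <- config$genotypes[1]
  mutants <- config$genotypes[-1]
  paths <- list()
  timings <- list()
  log_stage <- function(stage, msg) {
    message(sprintf("[%s] %s", stage, msg))
  }
  run_stage <- function(stage, fun) {
    t0 <- proc.time()[["elapsed"]]
    before <- unlist(paths)
    res <- tryCatch(fun(), error = function(e) {
      # keep partial outputs of the failed stage under a .partial suffix
      for (f in setdiff(unlist(paths), before)) {
        if (file.exists(f)) file.rename(f, paste0(f, ".partial"))
      }
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE)
    })
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  ## stage: inputs
  if (simulate) {
    input_dir <- file.path(outdir, "sim")
    run_stage("simulate", function() {
      log_stage("simulate", sprintf("seed %d -> %s", config$seed, input_dir))
      simulate_dataset(config, input_dir)
    })
  }
  need <- c("annotation.gff3", paste0("report_", c(wt, mutants), ".tsv"),
            "expression_counts.tsv", "sirna_counts.tsv", "sirna_libs.tsv")
  missing <- need[!file.exists(file.path(input_dir, need))]
  if (length(missing)) {
    stop_param("missing input file(s) in '%s': %s", input_dir,
               paste(missing, collapse = ", "))
  }
  inputs <- file.path(input_dir, need)

  ## stage: DMR calling per mutant
  n_tested <- integer(0)
  run_stage("dmr_calling", function() {
    sites_wt <- read_cytosine_report(file.path(input_dir,
                                               paste0("report_", wt, ".tsv")))
    for (m in mutants) {
      sites_m <- read_cytosine_report(file.path(input_dir,
                                                paste0("report_", m, ".tsv")))
      res <- call_dmrs(sites_wt, sites_m,
                       window_size = params$window_size,
                       min_coverage = params$min_coverage,
                       min_sites = params$min_sites,
                       context = params$context,
                       delta_min = params$delta_min, alpha = params$alpha,
                       max_gap = params$max_gap)
      f <- file.path(outdir, paste0("dmrs_", m, ".bed"))
      write_dmrs(res$dmrs, f)
      paths[[paste0("dmrs_", m)]] <<- f
      n_tested[m] <<- res$n_tested
      log_stage("dmr_calling",
                sprintf("%s vs %s: %d DMRs (%d hypo, %d hyper) from %d tested windows",
                        m, wt, nrow(res$dmrs),
                        sum(res$dmrs$direction == "hypo"),
                        sum(res$dmrs$direction == "hyper"), res$n_tested))
    }
    NULL
  })

  ## stage: DMR comparison between the first two mutants
  comparison <- NULL
  if (length(mutants) >= 2L) {
    run_stage("dmr_comparison", function() {
      a <- read_dmrs(paths[[paste0("dmrs_", mutants[1])]])
      b <- read_dmrs(paths[[paste0("dmrs_", mutants[2])]])
      ha <- a[a$direction == "hypo", , drop = FALSE]
      hb <- b[b$direction == "hypo", , drop = FALSE]
      part <- classify_overlap(ha, hb, min_overlap = params$min_overlap)
      universe <- min(n_tested[mutants[1]], n_tested[mutants[2]])
      enr <- dmr_overlap_enrichment(part, universe = universe)
      tab <- rbind(
        data.frame(set = mutants[1], ha,
                   shared = seq_len(nrow(ha)) %in% part$pairs$idx_a),
        data.frame(set = mutants[2], hb,
                   shared = seq_len(nrow(hb)) %in% part$pairs$idx_b))
      f <- file.path(outdir, "dmr_partition.tsv")
      utils::write.table(tab, f, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      paths$dmr_partition <<- f
      f2 <- file.path(outdir, "dmr_enrichment.tsv")
      utils::write.table(data.frame(k = enr$k, K = enr$K, n = enr$n,
                                    N = enr$N, p = enr$p),
                         f2, sep = "\t", quote = FALSE, row.names = FALSE)
      paths$dmr_enrichment <<- f2
      comparison <<- list(partition = part, enrichment = enr)
      log_stage("dmr_comparison",
                sprintf("hypo overlap > %d bp: %d/%d shared in %s, %d/%d in %s (hypergeometric p = %.3g, N = %d)",
                        params$min_overlap, part$counts["shared_a"],
                        part$counts["n_a"], mutants[1],
                        part$counts["shared_b"], part$counts["n_b"],
                        mutants[2], enr$p, universe))
      NULL
    })
  }

  ## stage: genomic composition of each DMR set
  ann <- read_features(file.path(input_dir, "annotation.gff3"))
  run_stage("composition", function() {
    comp <- do.call(rbind, lapply(mutants, function(m) {
      dm <- read_dmrs(paths[[paste0("dmrs_", m)]])
      cs <- genomic_composition(dm, ann)$summary
      data.frame(set = m, cs)
    }))
    f <- file.path(outdir, "dmr_composition.tsv")
    utils::write.table(comp, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths$dmr_composition <<- f
    NULL
  })

  ## stage: differential expression
  de_up <- list()
  run_stage("expression", function() {
    counts <- utils::read.table(file.path(input_dir,
                                          "expression_counts.tsv"),
                                header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
    for (m in mutants) {
      de <- call_differential_expression(counts, wt, m,
                                         fc_min = params$fc_min,
                                         alpha = params$de_alpha,
                                         pseudocount = params$de_pseudocount)
      f <- file.path(outdir, paste0("de_", m, ".tsv"))
      utils::write.table(de, f, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      paths[[paste0("de_", m)]] <<- f
      de_up[[m]] <<- split(de$feature_id[de$call == "up"],
                           de$kind[de$call == "up"])
      log_stage("expression", sprintf("%s vs %s: %d up, %d down",
                                      m, wt, sum(de$call == "up"),
                                      sum(de$call == "down")))
    }
    if (length(mutants) >= 2L) {
      rows <- list()
      for (kd in c("TE", "gene")) {
        up_a <- de_up[[mutants[1]]][[kd]] %||% character()
        up_b <- de_up[[mutants[2]]][[kd]] %||% character()
        part <- partition_targets(up_a, up_b)
        uni <- sum(counts$kind == kd)
        enr_p <- if (length(up_a) && length(up_b))
          set_enrichment(length(part$common), length(up_a),
                         length(up_b), uni) else NA_real_
        rows[[kd]] <- data.frame(
          kind = kd, up_a = length(up_a), up_b = length(up_b),
          common = length(part$common),
          specific_a = length(part$specific_a),
          specific_b = length(part$specific_b),
          universe = uni, p = enr_p,
          common_ids = paste(part$common, collapse = ","))
      }
      f <- file.path(outdir, "de_partition.tsv")
      utils::write.table(do.call(rbind, rows), f, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      paths$de_partition <<- f
    }
    NULL
  })

  ## stage: feature and promoter methylation
  run_stage("feature_methylation", function() {
    chrom_len <- NULL
    promoters <- promoter_regions(ann, params$promoter_len, chrom_len)
    tes <- ann[ann$kind == "TE", , drop = FALSE]
    lev <- list()
    for (g in c(wt, mutants)) {
      sites <- read_cytosine_report(file.path(input_dir,
                                              paste0("report_", g, ".tsv")))
      lev[[g]] <- rbind(
        cbind(region = "TE_body",
              feature_methylation_levels(sites, tes,
                                         params$min_coverage, g)),
        cbind(region = "promoter",
              feature_methylation_levels(sites, promoters,
                                         params$min_coverage, g)))
    }
    all_lev <- data.table::rbindlist(lev)
    f <- file.path(outdir, "feature_methylation.tsv")
    utils::write.table(all_lev, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths$feature_methylation <<- f

    wt_lev <- lev[[wt]]
    meth_te <- filter_methylated_features(
      wt_lev[wt_lev$region == "TE_body"], "TE",
      threshold = params$te_threshold)
    meth_prom <- filter_methylated_features(
      wt_lev[wt_lev$region == "promoter"], "gene-promoter",
      threshold = params$promoter_threshold)
    classes <- rbind(
      data.frame(feature_id = meth_te,
                 class = rep("methylated_TE", length(meth_te))),
      data.frame(feature_id = meth_prom,
                 class = rep("methylated_promoter", length(meth_prom))))
    f2 <- file.path(outdir, "methylated_features.tsv")
    utils::write.table(classes, f2, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths$methylated_features <<- f2

    deltas <- methylation_delta_table(
      data.table::rbindlist(lev)[region == "TE_body"], reference = wt)
    f3 <- file.path(outdir, "methylation_deltas.tsv")
    utils::write.table(deltas, f3, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths$methylation_deltas <<- f3
    NULL
  })

  ## stage: siRNA profiling
  sirna_prof <- NULL
  run_stage("sirna", function() {
    counts <- utils::read.table(file.path(input_dir, "sirna_counts.tsv"),
                                header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
    libs <- utils::read.table(file.path(input_dir, "sirna_libs.tsv"),
                              header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
    lib_totals <- stats::setNames(libs$library_total, libs$genotype)
    swt <- config$sirna_genotypes[1]
    smut <- config$sirna_genotypes[-1]
    prof <- sirna_profile(counts, lib_totals, wt = swt, mutants = smut,
                          dependence_cutoff = params$dependence_cutoff,
                          pseudocount = params$sirna_pseudocount,
                          min_wt_rptm = params$min_wt_rptm)
    f <- file.path(outdir, "sirna_profile.tsv")
    utils::write.table(prof, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths$sirna_profile <<- f
    sirna_prof <<- prof
    NULL
  })

  ## summary
  summary_rows <- list()
  add <- function(key, value) {
    summary_rows[[length(summary_rows) + 1L]] <<-
      data.frame(key = key, value = as.character(value))
  }
  for (m in mutants) {
    dm <- read_dmrs(paths[[paste0("dmrs_", m)]])
    add(paste0("n_hypo_dmrs_", m), sum(dm$direction == "hypo"))
    add(paste0("n_hyper_dmrs_", m), sum(dm$direction == "hyper"))
    add(paste0("n_tested_windows_", m), n_tested[m])
  }
  if (!is.null(comparison)) {
    cc <- comparison$partition$counts
    add("n_shared_hypo_a", cc["shared_a"])
    add("n_specific_hypo_a", cc["specific_a"])
    add("n_shared_hypo_b", cc["shared_b"])
    add("n_specific_hypo_b", cc["specific_b"])
    add("overlap_enrichment_p", formatC(comparison$enrichment$p,
                                        digits = 6, format = "g"))
  }
  for (m in mutants) {
    de <- utils::read.table(paths[[paste0("de_", m)]], header = TRUE,
                            sep = "\t", stringsAsFactors = FALSE)
    add(paste0("n_up_te_", m), sum(de$call == "up" & de$kind == "TE"))
    add(paste0("n_up_gene_", m), sum(de$call == "up" & de$kind == "gene"))
  }
  if (!is.null(sirna_prof)) {
    if ("pol_iv_dependent" %in% names(sirna_prof)) {
      add("n_pol_iv_dependent",
          sum(sirna_prof$pol_iv_dependent, na.rm = TRUE))
    }
    if ("pol_v_independent" %in% names(sirna_prof)) {
      add("n_pol_v_independent",
          sum(sirna_prof$pol_v_independent, na.rm = TRUE))
    }
  }
  summary <- do.call(rbind, summary_rows)
  paths$summary <- file.path(outdir, "summary.tsv")
  utils::write.table(summary, paths$summary, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  ## manifest
  out_files <- unlist(paths)
  manifest <- list(
    tool = "rddmr", version = as.character(utils::packageVersion("rddmr")),
    seed = config$seed, params = params,
    genotypes = config$genotypes, inputs = inputs,
    input_checksums = as.list(tools::md5sum(inputs)),
    outputs = as.list(out_files),
    output_checksums = as.list(tools::md5sum(unname(out_files))),
    stage_runtime_s = timings)
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  paths$manifest <- manifest_path
  invisible(list(outdir = outdir, paths = paths, summary = summary,
                 manifest = manifest))
}

#' Sensitivity and precision of interval recovery
#'
#' Matches called intervals to planted truth intervals under the strict
#' base-pair overlap rule (overlap must exceed `min_overlap`).
#' Sensitivity is the fraction of truth intervals recovered by at least
#' one call; precision the fraction of calls overlapping at least one
#' truth interval. An empty call set gives sensitivity 0 and precision
#' `NA` (flagged, not an error).
#'
#' @param called,truth Data frames with `chrom`, `start`, `end`
#'   (1-based closed).
#' @param min_overlap Overlap threshold in bp (default 50, strict).
#' @return List with `sensitivity`, `precision`, `n_called`, `n_truth`.
#' @export
interval_recovery <- function(called, truth, min_overlap = 50L) {
  if (nrow(called) == 0L) {
    return(list(sensitivity = 0, precision = NA_real_,
                n_called = 0L, n_truth = nrow(truth)))
  }
  part <- classify_overlap(called, truth, min_overlap = min_overlap)
  list(sensitivity = unname(part$counts["shared_b"] / nrow(truth)),
       precision = unname(part$counts["shared_a"] / nrow(called)),
       n_called = nrow(called), n_truth = nrow(truth))
}

#' Compare pipeline results against planted ground truth
#'
#' Computes recovery metrics for a simulated pipeline run: per-mutant
#' DMR sensitivity and precision under the >`min_overlap`-bp rule
#' (calls of the wrong direction count against precision),
#' differential-expression sensitivity and false-positive rate, and
#' siRNA dependence-label accuracy over informative planted features.
#'
#' @param outdir Pipeline output directory (as from
#'   [run_full_pipeline()]).
#' @param config The `"rddmr_config"` used for the run (source of the
#'   ground truth).
#' @param min_overlap Overlap threshold for DMR matching (default 50).
#' @return A data frame with columns `metric`, `genotype`, `value`.
#' @export
evaluate_against_truth <- function(outdir, config, min_overlap = 50L) {
  truth <- ground_truth(config)
  wt <- config$genotypes[1]
  mutants <- config$genotypes[-1]
  rows <- list()
  add <- function(metric, genotype, value) {
    rows[[length(rows) + 1L]] <<- data.frame(metric = metric,
                                             genotype = genotype,
                                             value = value)
  }
  for (m in mutants) {
    f <- file.path(outdir, paste0("dmrs_", m, ".bed"))
    if (!file.exists(f)) next
    called <- read_dmrs(f)
    tr <- truth$dmrs
    tr <- tr[vapply(strsplit(tr$genotypes, ",", fixed = TRUE),
                    function(g) m %in% trimws(g), logical(1)), ,
             drop = FALSE]
    hypo_called <- called[called$direction == "hypo", , drop = FALSE]
    rec <- interval_recovery(hypo_called, tr, min_overlap)
    add("dmr_sensitivity", m, rec$sensitivity)
    # precision over every called DMR, either direction
    rec_all <- interval_recovery(called, tr, min_overlap)
    add("dmr_precision", m, rec_all$precision)
    add("n_dmrs_called", m, nrow(called))
  }
  for (m in mutants) {
    f <- file.path(outdir, paste0("de_", m, ".tsv"))
    if (!file.exists(f)) next
    de <- utils::read.table(f, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    planted <- truth$de$feature_id[truth$de$genotype == m]
    up <- de$feature_id[de$call == "up"]
    nulls <- setdiff(de$feature_id, planted)
    add("de_sensitivity", m,
        if (length(planted)) mean(planted %in% up) else NA_real_)
    add("de_fp_rate", m,
        if (length(nulls)) mean(nulls %in% up) else NA_real_)
    add("de_precision", m,
        if (length(up)) mean(up %in% planted) else NA_real_)
  }
  f <- file.path(outdir, "sirna_profile.tsv")
  if (file.exists(f) && nrow(truth$sirna) > 0L) {
    prof <- utils::read.table(f, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
    tr <- truth$sirna
    m <- merge(tr, prof, by = "feature_id")
    m <- m[m$informative %in% TRUE, , drop = FALSE]
    if (nrow(m)) {
      correct <- c(m$pol_iv_dependent == (m$scale_nrpd1 < 0.5),
                   m$pol_v_independent == (m$scale_nrpe1 >= 0.5))
      add("sirna_label_accuracy", "all", mean(correct, na.rm = TRUE))
      add("n_sirna_informative", "all", nrow(m))
    }
  }
  do.call(rbind, rows)
}
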