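# A small configuration shared by the generator tests: 2 x 30 kb, a
# handful of features, one planted hypo-DMR affecting only the mutant.
small_config <- function(seed = 5L) {
  cfg <- simulation_config(seed = seed, n_chromosomes = 2L,
                           chromosome_length = 30000L,
                           n_genes = 8L, n_tes = 8L,
                           genotypes = c("WT", "mut"))
  ann <- simulate_annotation(cfg)
  te <- ann[ann$kind == "TE", ][1, ]
  cfg$planted_dmrs <- data.frame(
    dmr_id = "dmr_001", chrom = te$chrom, start = te$start,
    end = te$start + 299L, feature_id = te$feature_id,
    genotypes = "mut", direction = "hypo",
    delta_CG = -0.10, delta_CHG = -0.15, delta_CHH = -0.30,
    stringsAsFactors = FALSE)
  cfg$annotation <- ann
  cfg
}

test_that("generators are pure functions of (config, genotype)", {
  cfg <- small_config()
  expect_identical(simulate_annotation(simulation_config(seed = 5L)),
                   simulate_annotation(simulation_config(seed = 5L)))
  expect_identical(simulate_methylome(cfg, genotype = "WT"),
                   simulate_methylome(cfg, genotype = "WT"))
  expect_identical(simulate_expression(cfg, genotype = "mut"),
                   simulate_expression(cfg, genotype = "mut"))
  cfg$sirna_truth <- data.frame(feature_id = "TE_001", wt_mean = 100,
                                scale_nrpd1 = 0.02, scale_nrpe1 = 1,
                                label = "x", stringsAsFactors = FALSE)
  expect_identical(simulate_sirna(cfg, genotype = "nrpd1"),
                   simulate_sirna(cfg, genotype = "nrpd1"))
  # different genotypes draw from different streams
  expect_false(identical(simulate_methylome(cfg, genotype = "WT"),
                         simulate_methylome(cfg, genotype = "mut")))
})

test_that("simulated annotations are disjoint and in bounds", {
  cfg <- simulation_config(seed = 2L, n_chromosomes = 1L,
                           chromosome_length = 100000L,
                           n_genes = 10L, n_tes = 10L)
  ann <- simulate_annotation(cfg)
  expect_equal(nrow(ann), 20L)
  expect_true(all(ann$start >= 1 & ann$end <= 100000))
  byc <- ann[order(ann$start), ]
  expect_true(all(diff(byc$start) > 0))
  expect_true(all(byc$start[-1] > byc$end[-nrow(byc)]))
  # zero features -> empty annotation; oversized features -> error
  expect_equal(nrow(simulate_annotation(
    simulation_config(n_genes = 0L, n_tes = 0L))), 0L)
  expect_error(simulate_annotation(
    simulation_config(n_genes = 200L, chromosome_length = 10000L)),
    "exceed")
})

test_that("observed methylation converges to the configured baselines", {
  cfg <- small_config()
  ann <- cfg$annotation
  rep_wt <- simulate_methylome(cfg, ann, "WT")
  # weighted CG level over TE sites outside the planted DMR
  tes <- ann[ann$kind == "TE", ]
  gr <- GenomicRanges::GRanges(rep_wt$chrom,
                               IRanges::IRanges(rep_wt$pos, width = 1))
  in_te <- GenomicRanges::countOverlaps(
    gr, GenomicRanges::GRanges(tes$chrom,
                               IRanges::IRanges(tes$start, tes$end))) > 0
  cg <- rep_wt[in_te & rep_wt$context == "CG", ]
  lev <- sum(cg$count_meth) / sum(cg$count_meth + cg$count_unmeth)
  expect_equal(lev, 0.85, tolerance = 0.03)
})

test_that("planted deltas shift only the affected genotype", {
  cfg <- small_config()
  pd <- cfg$planted_dmrs
  in_dmr <- function(rep) rep$chrom == pd$chrom & rep$pos >= pd$start &
    rep$pos <= pd$end
  rep_wt <- simulate_methylome(cfg, genotype = "WT")
  rep_mut <- simulate_methylome(cfg, genotype = "mut")
  lev <- function(rep, cx) {
    s <- rep[in_dmr(rep) & rep$context == cx, ]
    sum(s$count_meth) / sum(s$count_meth + s$count_unmeth)
  }
  # CHH baseline 0.30 with delta -0.30 clamps to ~0 in the mutant only
  expect_lt(abs(lev(rep_wt, "CHH") - 0.30), 0.06)
  expect_lt(lev(rep_mut, "CHH"), 0.03)
  expect_lt(abs(lev(rep_mut, "CG") - 0.75), 0.10)
})

test_that("zero coverage produces an empty report", {
  cfg <- small_config()
  cfg$coverage_mean <- 0
  expect_equal(nrow(simulate_methylome(cfg, genotype = "WT")), 0L)
})

test_that("planted expression folds are recovered by the generator", {
  cfg <- de_benchmark_scenario(seed = 3L)
  wt <- simulate_expression(cfg, genotype = "WT")
  mut <- simulate_expression(cfg, genotype = "mutant")
  planted <- cfg$planted_de$feature_id
  ratio <- mean(mut$count[mut$feature_id %in% planted]) /
    mean(wt$count[wt$feature_id %in% planted])
  expect_equal(ratio, 4, tolerance = 0.15)
  # null features keep equal means
  nulls <- setdiff(wt$feature_id, planted)
  ratio0 <- mean(mut$count[mut$feature_id %in% nulls]) /
    mean(wt$count[wt$feature_id %in% nulls])
  expect_equal(ratio0, 1, tolerance = 0.05)
})

test_that("siRNA dependence scales apply per genotype", {
  cfg <- te_silencing_scenario(seed = 4L)
  wt <- simulate_sirna(cfg, genotype = "WT")
  nrpd1 <- simulate_sirna(cfg, genotype = "nrpd1")
  tr <- cfg$sirna_truth
  c24 <- function(tab, ids) {
    x <- tab[tab$read_length == 24L & tab$feature_id %in% ids, ]
    sum(x$count)
  }
  # library-size-corrected collapse to ~2% in nrpd1
  f_wt <- c24(wt, tr$feature_id) / unname(cfg$sirna_lib_totals["WT"] / 1e7)
  f_mu <- c24(nrpd1, tr$feature_id) /
    unname(cfg$sirna_lib_totals["nrpd1"] / 1e7)
  expect_equal(f_mu / f_wt, 0.02, tolerance = 0.3)
})

test_that("ground truth is consistent with the simulated genome", {
  cfg <- te_silencing_scenario(seed = 1L)
  ann <- simulate_annotation(cfg)
  truth <- ground_truth(cfg)
  expect_equal(nrow(truth$dmrs), 60L)
  expect_true(all(truth$dmrs$chrom %in% names(cfg$chromosomes)))
  expect_true(all(truth$dmrs$end <=
                    cfg$chromosomes[truth$dmrs$chrom]))
  expect_true(all(truth$de$feature_id %in% ann$feature_id))
  expect_true(all(truth$sirna$feature_id %in% ann$feature_id))
  # the planted morc6 up-set has no planted morc6 methylation change
  morc6_dmr_te <- truth$dmrs$feature_id[
    grepl("morc6", truth$dmrs$genotypes)]
  morc6_up <- truth$de$feature_id[truth$de$genotype == "morc6"]
  expect_length(intersect(morc6_up, morc6_dmr_te), 0L)
})

test_that("simulate_dataset writes a complete, reloadable bundle", {
  dir <- withr::local_tempdir()
  cfg <- small_config()
  cfg$sirna_genotypes <- c("WT", "nrpd1")
  cfg$sirna_lib_totals <- c(WT = 1e6, nrpd1 = 1e6)
  paths <- simulate_dataset(cfg, dir)
  expect_true(all(file.exists(unlist(paths))))
  ann <- read_features(paths$annotation)
  expect_equal(nrow(ann), 16L)
  rep_wt <- read_cytosine_report(paths$report_WT)
  expect_identical(rep_wt, simulate_methylome(cfg, genotype = "WT"))
  expr <- read.table(paths$expression, header = TRUE, sep = "\t")
  expect_true(all(c("WT", "mut") %in% names(expr)))
})
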