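test_that("promoters are the strand-aware 1-kb upstream interval", {
  genes <- make_features(start = c(5001L, 5001L), end = c(7000L, 7000L),
                         kind = "gene", strand = c("+", "-"),
                         id = c("gp", "gm"))
  prom <- promoter_regions(genes, promoter_len = 1000L)
  expect_equal(prom$start, c(4001L, 7001L))
  expect_equal(prom$end, c(5000L, 8000L))
  expect_equal(prom$kind, c("promoter", "promoter"))
  # promoter and gene are adjacent and disjoint on both strands
  expect_equal(prom$end[1] + 1L, genes$start[1])
  expect_equal(prom$start[2] - 1L, genes$end[2])
})

test_that("promoters truncate at chromosome bounds", {
  genes <- make_features(start = c(401L, 9501L), end = c(2000L, 9900L),
                         kind = "gene", strand = c("+", "-"),
                         id = c("g1", "g2"))
  prom <- promoter_regions(genes, promoter_len = 1000L,
                           chrom_lengths = c(Chr1 = 10000L))
  expect_equal(prom$start, c(1L, 9901L))
  expect_equal(prom$end, c(400L, 10000L))
})

test_that("promoters require a strand", {
  genes <- make_features(5001L, 7000L, "gene", strand = ".")
  expect_error(promoter_regions(genes), "strand")
})

test_that("feature methylation pools counts per context", {
  te <- make_features(1L, 100L, "TE", id = "te1")
  sites <- make_sites(pos = c(10L, 20L, 30L),
                      context = c("CG", "CG", "CHH"),
                      m = c(6L, 2L, 1L), u = c(2L, 0L, 9L))
  lev <- feature_methylation_levels(sites, te, min_coverage = 2)
  expect_equal(lev$level_CG, 0.8)
  expect_equal(lev$level_CHH, 0.1)
  expect_equal(lev$level_total, 9 / 20)
  expect_true(is.na(lev$level_CHG))
})

test_that("features with no qualifying site have undefined levels", {
  te <- make_features(1L, 100L, "TE", id = "te1")
  sites <- make_sites(pos = 10L, context = "CG", m = 2L, u = 2L)
  lev <- feature_methylation_levels(sites, te, min_coverage = 5)
  expect_true(is.na(lev$level_total))
  # feature with no cytosines at all
  lev2 <- feature_methylation_levels(sites[0, ], te)
  expect_true(is.na(lev2$level_total))
})

test_that("pooled feature level equals count-weighted window mean", {
  te <- make_features(1L, 200L, "TE", id = "te1")
  withr::with_seed(21, {
    sites <- make_sites(pos = sort(sample(1:200, 30)),
                        context = sample(c("CG", "CHG", "CHH"), 30, TRUE),
                        m = rbinom(30, 20, 0.4),
                        u = rbinom(30, 20, 0.5) + 1L)
  })
  lev <- feature_methylation_levels(sites, te, min_coverage = 5)
  win <- compute_window_methylation(sites, window_size = 50,
                                    min_coverage = 5)
  expect_equal(lev$level_total,
               sum(win$m_total) / sum(win$m_total + win$u_total))
})

test_that("methylation-class filters use strict thresholds", {
  mk <- function(level, id) {
    te <- make_features(1L, 100L, "TE", id = id)
    m <- as.integer(level * 1000)
    feature_methylation_levels(
      make_sites(10L, "CHH", m, 1000L - m), te)
  }
  feat <- data.table::rbindlist(list(mk(0.051, "a"), mk(0.050, "b"),
                                     mk(0.210, "c"), mk(0.200, "d")))
  expect_equal(filter_methylated_features(feat, "gene-promoter"),
               c("a", "c", "d"))
  expect_equal(filter_methylated_features(feat, "TE"), "c")
  # undefined levels are excluded with a message
  feat$level_total[1] <- NA
  expect_message(ids <- filter_methylated_features(feat, "TE"),
                 "undefined")
  expect_equal(ids, "c")
})

test_that("the group t-test is Welch's, with degenerate handling", {
  x <- c(0.1, 0.2, 0.3, 0.4)
  expect_equal(group_ttest(x, x)$p_value, 1)
  expect_equal(group_ttest(x, x)$statistic, 0)
  deg <- group_ttest(c(0, 0, 0, 0), c(1, 1, 1, 1))
  expect_true(deg$degenerate)
  expect_equal(deg$p_value, 0)
  expect_equal(deg$stars, "**")
  withr::with_seed(8, {
    g1 <- rnorm(50, 0.3, 0.05)
    g2 <- rnorm(50, 0.2, 0.05)
  })
  res <- group_ttest(g1, g2)
  ora <- oracle_welch(g1, g2)
  expect_equal(res$statistic, ora$t, tolerance = 1e-10)
  expect_equal(res$p_value, ora$p, tolerance = 1e-10)
  expect_error(group_ttest(c(1, 2), 3), "at least 2")
})

test_that("delta tables subtract the reference genotype", {
  te <- make_features(1L, 100L, "TE", id = "te1")
  lev_wt <- feature_methylation_levels(
    make_sites(10L, "CG", 50L, 50L), te, genotype = "WT")
  lev_mut <- feature_methylation_levels(
    make_sites(10L, "CG", 20L, 80L), te, genotype = "mut")
  d <- methylation_delta_table(rbind(lev_wt, lev_mut), "WT")
  expect_equal(d[d$context == "CG"]$delta, -0.3)
  expect_equal(d[d$context == "total"]$delta, -0.3)
  expect_true(is.na(d[d$context == "CHH"]$delta))   # undefined stays NA
  # identical genotypes give all-zero deltas
  lev_mut2 <- data.table::copy(lev_wt)[, genotype := "mut"]
  d2 <- methylation_delta_table(rbind(lev_wt, lev_mut2), "WT")
  expect_equal(d2[context %in% c("CG", "total")]$delta, c(0, 0))
  expect_error(methylation_delta_table(lev_wt, "nope"), "not present")
})
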