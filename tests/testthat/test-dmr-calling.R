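test_that("window methylation pools read counts, not per-site levels", {
  sites <- make_sites(pos = c(10L, 20L, 60L), context = "CG",
                      m = c(5L, 10L, 7L), u = c(5L, 0L, 3L))
  w <- compute_window_methylation(sites, window_size = 50, min_coverage = 5)
  expect_equal(nrow(w), 2L)
  expect_equal(w$start, c(1L, 51L))
  expect_equal(w$end, c(50L, 100L))
  expect_equal(w$level_CG[1], 15 / 20)   # pooled, not mean(0.5, 1)
  expect_equal(w$level_total[1], 0.75)
  expect_equal(w$n_CG, c(2L, 1L))
})

test_that("sites below the coverage threshold are excluded", {
  sites <- make_sites(pos = c(10L, 20L), context = "CG",
                      m = c(2L, 8L), u = c(2L, 2L))   # coverage 4 and 10
  w <- compute_window_methylation(sites, min_coverage = 5)
  expect_equal(w$n_CG, 1L)
  expect_equal(w$level_CG, 0.8)
  # no qualifying site in a grid cell -> no window emitted
  w2 <- compute_window_methylation(sites, min_coverage = 20)
  expect_equal(nrow(w2), 0L)
})

test_that("window parameters are validated", {
  sites <- make_sites(10L, "CG", 5L, 5L)
  expect_error(compute_window_methylation(sites, window_size = 0),
               "positive")
  expect_error(compute_window_methylation(sites, min_coverage = -1),
               "non-negative")
})

test_that("differential windows apply both thresholds", {
  mk <- function(m, u) {
    compute_window_methylation(make_sites(10L, "CG", m, u),
                               min_coverage = 1)
  }
  # strong difference: 0.8 vs 0.2 on 50 reads per genotype
  wa <- mk(40L, 10L); wb <- mk(10L, 40L)
  dw <- call_differential_windows(wa, wb)
  expect_equal(nrow(dw), 1L)
  expect_equal(dw$delta, -0.6)
  expect_equal(dw$direction, "hypo")
  expect_equal(dw$p, oracle_fisher2x2(40, 10, 10, 40), tolerance = 1e-12)

  # |delta| below 0.10 is never retained, however significant
  wa <- mk(5000L, 5000L); wb <- mk(4100L, 5900L)
  dw <- call_differential_windows(wa, wb)
  expect_equal(nrow(dw), 0L)

  # significant delta but p above alpha is not retained
  wa <- mk(6L, 4L); wb <- mk(3L, 7L)
  expect_gt(fisher_exact_two_sided(6, 4, 3, 7), 0.01)
  expect_equal(nrow(call_differential_windows(wa, wb)), 0L)
})

test_that("the delta boundary is inclusive by default", {
  mk <- function(m, u) compute_window_methylation(
    make_sites(pos = 10L, context = "CG", m = m, u = u), min_coverage = 1)
  wa <- mk(600L, 400L); wb <- mk(500L, 500L)   # delta exactly -0.10
  expect_equal(nrow(call_differential_windows(wa, wb)), 1L)
  expect_equal(nrow(call_differential_windows(wa, wb,
                                              inclusive_delta = FALSE)), 0L)
})

test_that("mismatched window grids raise an alignment error", {
  wa <- compute_window_methylation(make_sites(10L, "CG", 8L, 2L),
                                   window_size = 50)
  wb <- compute_window_methylation(make_sites(10L, "CG", 8L, 2L),
                                   window_size = 100)
  expect_error(call_differential_windows(wa, wb), "grids do not align")
})

test_that("window merging honors the gap boundary exactly", {
  # gap of exactly 50 bp merges ...
  dw <- make_diff_windows(start = c(1L, 101L), end = c(50L, 150L),
                          direction = "hypo")
  m <- merge_windows(dw, max_gap = 50)
  expect_equal(nrow(m), 1L)
  expect_equal(c(m$start, m$end), c(1L, 150L))
  expect_equal(m$n_windows, 2L)
  # ... a gap of 51 bp does not
  dw <- make_diff_windows(start = c(1L, 102L), end = c(50L, 151L),
                          direction = "hypo")
  expect_equal(nrow(merge_windows(dw, max_gap = 50)), 2L)
})

test_that("hypo and hyper chains are never mixed", {
  dw <- make_diff_windows(start = c(1L, 51L), end = c(50L, 100L),
                          direction = c("hypo", "hyper"))
  m <- merge_windows(dw, max_gap = 50)
  expect_equal(nrow(m), 2L)
  expect_setequal(m$direction, c("hypo", "hyper"))
})

test_that("DMR deltas are recomputed from pooled counts", {
  dw <- make_diff_windows(start = c(1L, 51L), end = c(50L, 100L),
                          direction = "hypo",
                          m_a = c(40L, 20L), u_a = c(10L, 30L),
                          m_b = c(10L, 5L), u_b = c(40L, 45L))
  m <- merge_windows(dw)
  expect_equal(m$delta_total, 15 / 100 - 60 / 100)
  expect_equal(m$p_min, 1e-6)
})

test_that("merging is idempotent and conserves windows", {
  withr::with_seed(11, {
    for (rep in 1:20) {
      n <- sample(1:30, 1)
      starts <- sort(sample(seq(1, 5000, by = 50), n))
      dw <- make_diff_windows(
        start = starts, end = starts + 49L,
        direction = sample(c("hypo", "hyper"), n, TRUE),
        chrom = sample(c("Chr1", "Chr2"), n, TRUE))
      m <- merge_windows(dw, max_gap = 50)
      # conservation: every window in exactly one DMR
      expect_equal(sum(m$n_windows), n)
      within <- vapply(seq_len(n), function(i) {
        sum(m$chrom == dw$chrom[i] & m$start <= dw$start[i] &
              m$end >= dw$end[i] & m$direction == dw$direction[i])
      }, numeric(1))
      expect_true(all(within >= 1))
      # idempotence: re-merging the regions reproduces them
      m2 <- merge_windows(
        transform(m[, c("chrom", "start", "end", "direction")],
                  m_a = 40L, u_a = 10L, m_b = 10L, u_b = 40L, p = 1e-6),
        max_gap = 50)
      expect_equal(m2[, c("chrom", "start", "end", "direction")],
                   as.data.frame(m)[, c("chrom", "start", "end",
                                        "direction")],
                   ignore_attr = TRUE)
    }
  })
})

test_that("call_dmrs recovers a constructed differential region", {
  # 6 CG sites per window across 4 windows; middle two windows lose
  # methylation in genotype B
  pos <- as.integer(seq(5, 200, by = 8))
  sites_a <- make_sites(pos, "CG", m = 16L, u = 4L)       # level 0.8
  mB <- ifelse(pos > 50 & pos <= 150, 4L, 16L)            # level 0.2 inside
  sites_b <- make_sites(pos, "CG", m = mB,
                        u = ifelse(pos > 50 & pos <= 150, 16L, 4L))
  res <- call_dmrs(sites_a, sites_b)
  expect_equal(nrow(res$dmrs), 1L)
  expect_equal(res$dmrs$direction, "hypo")
  expect_equal(c(res$dmrs$start, res$dmrs$end), c(51L, 150L))
  expect_equal(res$n_tested, 4L)
})
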