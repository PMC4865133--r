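#' Pool cytosine counts into fixed-width windows
#'
#' Tiles each chromosome with non-overlapping windows of `window_size`
#' base pairs, anchored at coordinate 0, and pools read counts of the
#' qualifying sites per window and per context. A site qualifies when its
#' coverage (`count_meth + count_unmeth`) is at least `min_coverage`.
#' Window methylation is the weighted level: pooled methylated reads over
#' pooled total reads, not a mean of per-site levels. Windows with no
#' qualifying site are not emitted.
#'
#' @param sites Cytosine report data frame (see [read_cytosine_report()]).
#' @param window_size Window width in bp (default 50).
#' @param min_coverage Minimum per-site read coverage (default 5).
#' @param min_sites Minimum number of qualifying sites for a window to be
#'   emitted (default 1).
#' @return A `data.table` keyed by (`chrom`, `start`) with 1-based closed
#'   window coordinates and, for each context `c` in CG/CHG/CHH and for
#'   `total`: pooled counts `m_c`, `u_c`, site count `n_c` and
#'   `level_c` (`NA` where no reads).
#' @export
compute_window_methylation <- function(sites, window_size = 50L,
                                       min_coverage = 5L, min_sites = 1L) {
  if (length(window_size) != 1L || is.na(window_size) || window_size <= 0) {
    stop_param("window_size must be a positive integer")
  }
  if (length(min_coverage) != 1L || is.na(min_coverage) || min_coverage < 0) {
    stop_param("min_coverage must be non-negative")
  }
  window_size <- as.integer(window_size)
  dt <- data.table::as.data.table(sites)
  dt <- dt[count_meth + count_unmeth >= min_coverage]
  if (nrow(dt) == 0L) return(.empty_window_table(window_size))

  dt[, wstart := ((pos - 1L) %/% window_size) * window_size + 1L]
  agg <- dt[, list(m = sum(count_meth), u = sum(count_unmeth), n = .N),
            by = list(chrom, start = wstart, context)]
  wide <- data.table::dcast(agg, chrom + start ~ context,
                            value.var = c("m", "u", "n"), fill = 0L)
  for (cx in CONTEXTS) {
    for (pre in c("m_", "u_", "n_")) {
      col <- paste0(pre, cx)
      if (!col %in% names(wide)) wide[, (col) := 0L]
    }
  }
  wide[, `:=`(m_total = m_CG + m_CHG + m_CHH,
              u_total = u_CG + u_CHG + u_CHH,
              n_total = n_CG + n_CHG + n_CHH)]
  wide <- wide[n_total >= min_sites]
  wide[, end := start + window_size - 1L]
  for (cx in c(CONTEXTS, "total")) {
    m <- wide[[paste0("m_", cx)]]
    u <- wide[[paste0("u_", cx)]]
    wide[, (paste0("level_", cx)) := ifelse(m + u > 0, m / (m + u), NA_real_)]
  }
  data.table::setcolorder(wide, c("chrom", "start", "end"))
  data.table::setkeyv(wide, c("chrom", "start"))
  data.table::setattr(wide, "window_size", window_size)
  wide[]
}

.empty_window_table <- function(window_size) {
  cols <- c("chrom", "start", "end",
            as.vector(outer(c("m_", "u_", "n_", "level_"),
                            c(CONTEXTS, "total"), paste0)))
  out <- data.table::as.data.table(
    stats::setNames(rep(list(integer(0)), length(cols)), cols))
  out[, chrom := character(0)]
  for (cx in c(CONTEXTS, "total")) {
    out[, (paste0("level_", cx)) := numeric(0)]
  }
  data.table::setattr(out, "window_size", as.integer(window_size))
  out[]
}

#' Test windows for differential methylation between two genotypes
#'
#' For every window present in both genotypes (with at least one read on
#' the tested context set in each), computes the methylation difference
#' `delta = level_B - level_A` on pooled counts and a two-sided Fisher
#' exact p-value on the 2x2 table of pooled methylated/unmethylated
#' reads. Windows are retained when `|delta| >= delta_min` and
#' `p < alpha`; the boundary at `delta_min` is inclusive by default
#' (`inclusive_delta = FALSE` switches to strict). Retained windows are
#' tagged `hypo` (lower in B) or `hyper`.
#'
#' @param windows_a,windows_b Window tables from
#'   [compute_window_methylation()] on the same grid; A is the reference
#'   genotype (e.g. wild type), B the test genotype.
#' @param context One of `"total"`, `"CG"`, `"CHG"`, `"CHH"`: which
#'   pooled counts to test. The default tests all cytosines together;
#'   per-context calling stratifies the same machinery.
#' @param delta_min Minimum absolute methylation difference (default
#'   0.10).
#' @param alpha Significance threshold on the raw Fisher p-value
#'   (default 0.01). No multiple-testing correction is applied by
#'   default, matching the thresholding procedure this implements;
#'   `fdr = TRUE` switches the p-value cut to Benjamini-Hochberg
#'   adjusted values.
#' @param inclusive_delta Whether `|delta| == delta_min` passes.
#' @param keep_all Return all tested windows with a `significant` flag
#'   instead of only the retained ones.
#' @param fdr Apply BH adjustment before thresholding (default `FALSE`).
#' @return A `data.table` of differential windows with pooled counts,
#'   levels, `delta`, `p` and `direction`; the number of tested windows
#'   is stored in the `"n_tested"` attribute.
#' @export
call_differential_windows <- function(windows_a, windows_b,
                                      context = "total", delta_min = 0.10,
                                      alpha = 0.01, inclusive_delta = TRUE,
                                      keep_all = FALSE, fdr = FALSE) {
  if (!context %in% c("total", CONTEXTS)) {
    stop_param("context must be one of total, CG, CHG, CHH")
  }
  ws_a <- attr(windows_a, "window_size") %||%
    (windows_a$end[1] - windows_a$start[1] + 1L)
  ws_b <- attr(windows_b, "window_size") %||%
    (windows_b$end[1] - windows_b$start[1] + 1L)
  if (!is.null(ws_a) && !is.null(ws_b) && !identical(ws_a, ws_b)) {
    stop_param("window grids do not align: window sizes %s and %s", ws_a, ws_b)
  }
  mcol <- paste0("m_", context); ucol <- paste0("u_", context)
  a <- data.table::as.data.table(windows_a)[, c("chrom", "start", "end",
                                                mcol, ucol), with = FALSE]
  data.table::setnames(a, c(mcol, ucol), c("m_a", "u_a"))
  b <- data.table::as.data.table(windows_b)[, c("chrom", "start", "end",
                                                mcol, ucol), with = FALSE]
  data.table::setnames(b, c(mcol, ucol), c("m_b", "u_b"))
  tested <- merge(a, b, by = c("chrom", "start", "end"))
  if (nrow(tested) == 0L && nrow(a) > 0L && nrow(b) > 0L &&
      length(intersect(a$chrom, b$chrom)) > 0L) {
    stop_param("window grids do not align: no common windows on shared chromosomes")
  }
  tested <- tested[m_a + u_a > 0 & m_b + u_b > 0]
  tested[, `:=`(level_a = m_a / (m_a + u_a), level_b = m_b / (m_b + u_b))]
  tested[, delta := level_b - level_a]
  tested[, p := fisher_exact_two_sided(m_a, u_a, m_b, u_b)]
  p_cut <- if (fdr) stats::p.adjust(tested$p, "BH") else tested$p
  # 1e-9 guard so a difference of exactly delta_min is not lost to
  # floating-point noise in level_b - level_a
  pass_delta <- if (inclusive_delta) {
    abs(tested$delta) >= delta_min - 1e-9
  } else {
    abs(tested$delta) > delta_min + 1e-9
  }
  tested[, significant := pass_delta & p_cut < alpha]
  tested[, direction := data.table::fifelse(delta < 0, "hypo", "hyper")]
  n_tested <- nrow(tested)
  out <- if (keep_all) tested else tested[significant == TRUE,
                                          !"significant"]
  data.table::setorderv(out, c("chrom", "start"))
  data.table::setattr(out, "n_tested", n_tested)
  data.table::setattr(out, "window_size",
                      ws_a %||% ws_b)
  out[]
}

#' Merge proximal differential windows into DMRs
#'
#' Chains same-chromosome, same-direction differential windows whose gap
#' (bases strictly between consecutive windows) is at most `max_gap`
#' into one differentially methylated region spanning the first to the
#' last window. Hypo and hyper chains are never mixed. The region-level
#' methylation difference `delta_total` is recomputed from counts pooled
#' over all constituent windows, and `p_min` is the smallest window
#' p-value.
#'
#' @param diff_windows Output of [call_differential_windows()].
#' @param max_gap Maximum gap in bp between merged windows (default 50;
#'   a gap of exactly `max_gap` still merges).
#' @return A `data.table` of DMRs with columns `chrom`, `start`, `end`
#'   (1-based closed), `direction`, `n_windows`, `delta_total`, `p_min`,
#'   sorted by (chrom, start).
#' @export
merge_windows <- function(diff_windows, max_gap = 50L) {
  empty <- data.table::data.table(
    chrom = character(), start = integer(), end = integer(),
    direction = character(), n_windows = integer(),
    delta_total = numeric(), p_min = numeric())
  dw <- data.table::as.data.table(diff_windows)
  if (nrow(dw) == 0L) return(empty)
  data.table::setorderv(dw, c("direction", "chrom", "start"))
  dw[, grp := cumsum(
    c(1L, as.integer(chrom[-1L] != chrom[-.N] |
                     direction[-1L] != direction[-.N] |
                     (start[-1L] - end[-.N] - 1L) > max_gap)))]
  dmrs <- dw[, list(
    chrom = chrom[1L], start = min(start), end = max(end),
    direction = direction[1L], n_windows = .N,
    delta_total = sum(m_b) / (sum(m_b) + sum(u_b)) -
      sum(m_a) / (sum(m_a) + sum(u_a)),
    p_min = min(p)), by = grp][, !"grp"]
  data.table::setorderv(dmrs, c("chrom", "start"))
  dmrs[]
}

#' Call DMRs between two genotypes from cytosine reports
#'
#' Convenience wrapper running the full window procedure: per-genotype
#' 50-bp window methylation with the 5x site-coverage filter, the
#' two-sided Fisher exact test with the 10% difference and p < 0.01
#' thresholds, and merging of proximal significant windows (gap <= 50
#' bp) into DMRs. All thresholds are arguments; the defaults are the
#' procedure's published values.
#'
#' @param sites_a,sites_b Cytosine reports for the reference (A) and
#'   test (B) genotypes.
#' @param window_size,min_coverage,min_sites See
#'   [compute_window_methylation()].
#' @param context,delta_min,alpha,inclusive_delta,fdr See
#'   [call_differential_windows()].
#' @param max_gap See [merge_windows()].
#' @return A list with elements `dmrs`, `diff_windows`, `n_tested`
#'   (number of windows tested, the natural enrichment universe) and
#'   `params`.
#' @export
call_dmrs <- function(sites_a, sites_b, window_size = 50L,
                      min_coverage = 5L, min_sites = 1L,
                      context = "total", delta_min = 0.10, alpha = 0.01,
                      inclusive_delta = TRUE, fdr = FALSE, max_gap = 50L) {
  wa <- compute_window_methylation(sites_a, window_size, min_coverage,
                                   min_sites)
  wb <- compute_window_methylation(sites_b, window_size, min_coverage,
                                   min_sites)
  dwin <- call_differential_windows(wa, wb, context = context,
                                    delta_min = delta_min, alpha = alpha,
                                    inclusive_delta = inclusive_delta,
                                    fdr = fdr)
  dmrs <- merge_windows(dwin, max_gap = max_gap)
  list(dmrs = dmrs, diff_windows = dwin,
       n_tested = attr(dwin, "n_tested"),
       params = list(window_size = window_size, min_coverage = min_coverage,
                     min_sites = min_sites, context = context,
                     delta_min = delta_min, alpha = alpha,
                     inclusive_delta = inclusive_delta, fdr = fdr,
                     max_gap = max_gap))
}
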