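#' Derive 1-kb promoter intervals from gene annotations
#'
#' The promoter is the `promoter_len` bases immediately upstream of the
#' gene's 5' end on its coding strand: `[start - L, start - 1]` for
#' plus-strand genes and `[end + 1, end + L]` for minus-strand genes
#' (1-based closed). Promoters are truncated at chromosome bounds when
#' `chrom_lengths` is given; overlaps with neighboring genes are allowed
#' (no clipping). Genes whose promoter is fully outside the chromosome
#' are dropped with a warning.
#'
#' @param features Annotation data frame; only rows with
#'   `kind == "gene"` are used. Strand must be `+` or `-`.
#' @param promoter_len Promoter length in bp (default 1000).
#' @param chrom_lengths Optional named vector of chromosome lengths for
#'   truncation at the right end.
#' @return A feature data frame with `kind = "promoter"` and the parent
#'   gene's `feature_id` and strand.
#' @export
promoter_regions <- function(features, promoter_len = 1000L,
                             chrom_lengths = NULL) {
  genes <- features[features$kind == "gene", , drop = FALSE]
  if (nrow(genes) == 0L) {
    return(data.frame(feature_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), kind = character(),
                      stringsAsFactors = FALSE))
  }
  if (any(!genes$strand %in% c("+", "-"))) {
    stop_param("promoter undefined for genes without strand: %s",
               genes$feature_id[!genes$strand %in% c("+", "-")][1])
  }
  plus <- genes$strand == "+"
  start <- ifelse(plus, genes$start - promoter_len, genes$end + 1L)
  end <- ifelse(plus, genes$start - 1L, genes$end + promoter_len)
  start <- pmax(start, 1L)
  if (!is.null(chrom_lengths)) {
    lim <- unname(chrom_lengths[genes$chrom])
    end <- pmin(end, ifelse(is.na(lim), end, lim))
  }
  keep <- start <= end
  if (any(!keep)) {
    warning(sprintf("%d promoter(s) fall entirely outside the chromosome and were dropped",
                    sum(!keep)))
  }
  data.frame(feature_id = genes$feature_id[keep],
             chrom = genes$chrom[keep],
             start = as.integer(start[keep]), end = as.integer(end[keep]),
             strand = genes$strand[keep],
             kind = rep("promoter", sum(keep)),
             stringsAsFactors = FALSE)
}

#' Feature-level methylation by pooled read counts
#'
#' Estimates the methylation level of each feature (TE body, gene body
#' or promoter) by pooling the read counts of all sites inside the
#' feature that pass the per-site coverage filter, separately per
#' context and for all cytosines together. Contexts with no qualifying
#' reads are `NA` (undefined), never zero-filled.
#'
#' @param sites Cytosine report data frame.
#' @param features Feature or promoter data frame.
#' @param min_coverage Minimum per-site coverage (default 5).
#' @param genotype Optional label stored in a `genotype` column.
#' @return A `data.table` with one row per feature: pooled `m_*`,
#'   `u_*`, `n_*` and `level_*` for CG, CHG, CHH and total. Features
#'   with no qualifying site keep all levels `NA`.
#' @export
feature_methylation_levels <- function(sites, features, min_coverage = 5L,
                                       genotype = NA_character_) {
  dt <- data.table::as.data.table(sites)
  dt <- dt[count_meth + count_unmeth >= min_coverage]
  base <- data.table::data.table(feature_id = features$feature_id,
                                 kind = features$kind)
  if (nrow(dt) > 0L && nrow(features) > 0L) {
    gs <- GenomicRanges::GRanges(dt$chrom, IRanges::IRanges(dt$pos, width = 1L))
    gf <- features_granges(features)
    h <- GenomicRanges::findOverlaps(gs, gf, ignore.strand = TRUE)
    hit <- data.table::data.table(
      feature_id = features$feature_id[S4Vectors::subjectHits(h)],
      context = dt$context[S4Vectors::queryHits(h)],
      m = dt$count_meth[S4Vectors::queryHits(h)],
      u = dt$count_unmeth[S4Vectors::queryHits(h)])
    agg <- hit[, list(m = sum(m), u = sum(u), n = .N),
               by = list(feature_id, context)]
    wide <- data.table::dcast(agg, feature_id ~ context,
                              value.var = c("m", "u", "n"), fill = 0L)
  } else {
    wide <- data.table::data.table(feature_id = character())
  }
  for (cx in CONTEXTS) {
    for (pre in c("m_", "u_", "n_")) {
      col <- paste0(pre, cx)
      if (!col %in% names(wide)) wide[, (col) := 0L]
    }
  }
  out <- merge(base, wide, by = "feature_id", all.x = TRUE, sort = FALSE)
  for (col in grep("^(m|u|n)_", names(out), value = TRUE)) {
    data.table::set(out, which(is.na(out[[col]])), col, 0L)
  }
  out[, `:=`(m_total = m_CG + m_CHG + m_CHH,
             u_total = u_CG + u_CHG + u_CHH,
             n_total = n_CG + n_CHG + n_CHH)]
  for (cx in c(CONTEXTS, "total")) {
    m <- out[[paste0("m_", cx)]]
    u <- out[[paste0("u_", cx)]]
    out[, (paste0("level_", cx)) := ifelse(m + u > 0, m / (m + u),
                                           NA_real_)]
  }
  out[, genotype := genotype]
  out[]
}

#' Filter features by methylation class
#'
#' The methylation-class rule used to select loci for box plots and
#' correlation analyses: a TE body is "significantly methylated" when
#' its total-cytosine level exceeds 20%, a gene promoter when it exceeds
#' 5% (strict inequalities). Features with undefined (NA) levels are
#' excluded with a message.
#'
#' @param feat_meth Output of [feature_methylation_levels()].
#' @param kind `"TE"` or `"gene-promoter"`; selects the default
#'   threshold.
#' @param threshold Override for the level threshold (proportion).
#' @return Character vector of retained feature ids.
#' @export
filter_methylated_features <- function(feat_meth,
                                       kind = c("TE", "gene-promoter"),
                                       threshold = NULL) {
  kind <- match.arg(kind)
  threshold <- threshold %||% if (kind == "TE") 0.20 else 0.05
  lev <- feat_meth$level_total
  undef <- is.na(lev)
  if (any(undef)) {
    message(sprintf("%d feature(s) with undefined methylation level excluded",
                    sum(undef)))
  }
  feat_meth$feature_id[!undef & lev > threshold]
}

#' Welch two-sample t-test with significance stars
#'
#' Two-sided unequal-variance t-test between two groups of methylation
#' levels, reported with the conventional star annotation (* p < 0.05,
#' ** p < 0.01). When both groups have zero variance the statistic
#' degenerates: identical means give t = 0, p = 1; different means give
#' p = 0 with a `degenerate` flag.
#'
#' @param x,y Numeric vectors, each with at least two non-missing
#'   values.
#' @return List with `statistic`, `p_value`, `df`, `stars` and
#'   `degenerate`.
#' @export
group_ttest <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L) {
    stop_param("each group needs at least 2 defined values")
  }
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y)) {
      res <- list(statistic = 0, p_value = 1, df = NA_real_,
                  degenerate = TRUE)
    } else {
      res <- list(statistic = sign(mean(x) - mean(y)) * Inf, p_value = 0,
                  df = NA_real_, degenerate = TRUE)
    }
  } else {
    tt <- stats::t.test(x, y, var.equal = FALSE)
    res <- list(statistic = unname(tt$statistic),
                p_value = tt$p.value, df = unname(tt$parameter),
                degenerate = FALSE)
  }
  res$stars <- if (res$p_value < 0.01) "**" else
    if (res$p_value < 0.05) "*" else ""
  res
}

#' Per-feature methylation differences against a reference genotype
#'
#' Long-format table of `level(genotype) - level(reference)` per feature
#' and context — the data behind delta heat maps and scatter plots in
#' which the wild-type level is set to 0. Deltas involving an undefined
#' level are `NA`.
#'
#' @param feat_meth_all Row-bound outputs of
#'   [feature_methylation_levels()] for several genotypes (the
#'   `genotype` column distinguishes them).
#' @param reference Reference genotype label (e.g. `"WT"`).
#' @return A `data.table` with `feature_id`, `genotype`, `context`,
#'   `level`, `level_ref`, `delta` for every non-reference genotype.
#' @export
methylation_delta_table <- function(feat_meth_all, reference) {
  dt <- data.table::as.data.table(feat_meth_all)
  if (!reference %in% dt$genotype) {
    stop_param("reference genotype '%s' not present", reference)
  }
  lvl_cols <- paste0("level_", c(CONTEXTS, "total"))
  long <- data.table::melt(dt[, c("feature_id", "genotype", lvl_cols),
                              with = FALSE],
                           id.vars = c("feature_id", "genotype"),
                           variable.name = "context", value.name = "level")
  long[, context := sub("^level_", "", context)]
  ref <- long[genotype == reference,
              list(feature_id, context, level_ref = level)]
  out <- merge(long[genotype != reference], ref,
               by = c("feature_id", "context"))
  out[, delta := level - level_ref]
  data.table::setorderv(out, c("genotype", "feature_id", "context"))
  out[]
}
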