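#' Partition two DMR sets into shared and specific regions
#'
#' Two DMRs are considered overlapping only when their overlap exceeds
#' `min_overlap` base pairs (strictly: an overlap of exactly
#' `min_overlap` does not count). Each DMR of set A is "shared" when at
#' least one DMR of set B overlaps it by more than `min_overlap` bp, and
#' "specific" otherwise; symmetrically for B. A DMR with several
#' qualifying partners is counted once in the partition, but every
#' qualifying pair is listed. Overlap is measured against each single
#' partner, not aggregated across partners.
#'
#' In the two-mutant comparison this partition is the Class I / Class II
#' split: shared hypo-DMRs (Class I) versus mutant-specific ones
#' (Class II).
#'
#' @param dmrs_a,dmrs_b DMR data frames (1-based closed coordinates).
#' @param min_overlap Overlap threshold in bp (default 50, strict).
#' @return A list of class `"dmr_overlap_partition"` with elements
#'   `shared_a`, `specific_a`, `shared_b`, `specific_b` (row subsets of
#'   the inputs), `pairs` (`idx_a`, `idx_b`, `overlap_bp`) and `counts`.
#' @export
classify_overlap <- function(dmrs_a, dmrs_b, min_overlap = 50L) {
  dmrs_a <- as.data.frame(dmrs_a)
  dmrs_b <- as.data.frame(dmrs_b)
  ga <- dmr_granges(dmrs_a)
  gb <- dmr_granges(dmrs_b)
  pairs <- data.frame(idx_a = integer(), idx_b = integer(),
                      overlap_bp = integer())
  if (length(ga) > 0L && length(gb) > 0L) {
    h <- GenomicRanges::findOverlaps(ga, gb, ignore.strand = TRUE)
    if (length(h) > 0L) {
      ov <- GenomicRanges::width(GenomicRanges::pintersect(
        ga[S4Vectors::queryHits(h)], gb[S4Vectors::subjectHits(h)]))
      keep <- ov > min_overlap
      pairs <- data.frame(idx_a = S4Vectors::queryHits(h)[keep],
                          idx_b = S4Vectors::subjectHits(h)[keep],
                          overlap_bp = as.integer(ov[keep]))
    }
  }
  in_a <- seq_len(nrow(dmrs_a)) %in% pairs$idx_a
  in_b <- seq_len(nrow(dmrs_b)) %in% pairs$idx_b
  out <- list(
    shared_a = dmrs_a[in_a, , drop = FALSE],
    specific_a = dmrs_a[!in_a, , drop = FALSE],
    shared_b = dmrs_b[in_b, , drop = FALSE],
    specific_b = dmrs_b[!in_b, , drop = FALSE],
    pairs = pairs,
    counts = c(n_a = nrow(dmrs_a), n_b = nrow(dmrs_b),
               shared_a = sum(in_a), specific_a = sum(!in_a),
               shared_b = sum(in_b), specific_b = sum(!in_b)),
    min_overlap = min_overlap)
  class(out) <- "dmr_overlap_partition"
  out
}

#' @export
print.dmr_overlap_partition <- function(x, ...) {
  cat(sprintf(
    "DMR overlap partition (overlap > %d bp)\n  set A: %d (%d shared, %d specific)\n  set B: %d (%d shared, %d specific)\n  qualifying pairs: %d\n",
    x$min_overlap, x$counts["n_a"], x$counts["shared_a"],
    x$counts["specific_a"], x$counts["n_b"], x$counts["shared_b"],
    x$counts["specific_b"], nrow(x$pairs)))
  invisible(x)
}

#' Hypergeometric enrichment of a DMR overlap
#'
#' Tests whether the number of set-B DMRs overlapping set A is higher
#' than expected by chance when drawing `n_b` regions from a universe of
#' `universe` comparable regions containing `n_a` marked ones.
#'
#' The universe is a required argument because it is analysis-dependent:
#' for window-derived DMR sets the number of tested windows is the
#' natural choice ([call_dmrs()] reports it as `n_tested`); for
#' feature-level comparisons the number of annotated features is.
#'
#' @param partition A `"dmr_overlap_partition"` from [classify_overlap()],
#'   or the overlap count `k` directly.
#' @param n_a,n_b Set sizes (ignored when `partition` is a partition
#'   object).
#' @param universe Universe size `N`.
#' @return A list with `k`, `K`, `n`, `N` and the upper-tail `p`.
#' @export
dmr_overlap_enrichment <- function(partition, n_a = NULL, n_b = NULL,
                                   universe) {
  if (inherits(partition, "dmr_overlap_partition")) {
    k <- unname(partition$counts["shared_b"])
    n_a <- unname(partition$counts["n_a"])
    n_b <- unname(partition$counts["n_b"])
  } else {
    k <- partition
  }
  list(k = k, K = n_a, n = n_b, N = universe,
       p = hypergeometric_upper_tail(k, n_a, n_b, universe))
}

#' Classify DMRs by genomic location
#'
#' Assigns each DMR to gene, TE or other (unannotated) space by maximal
#' base-pair overlap, with ties broken in the order TE > gene > other,
#' and summarizes the assignment as percentages of the DMR count.
#'
#' @param dmrs DMR data frame.
#' @param features Annotation data frame with `kind` in gene/TE
#'   (see [read_features()]); space covered by neither is "other".
#' @return A list with `assignment` (per-DMR overlap bp and assigned
#'   `kind`) and `summary` (`kind`, `n`, `percent`; percentages sum to
#'   100). An empty DMR set yields empty tables with attribute
#'   `empty = TRUE`, not an error.
#' @export
genomic_composition <- function(dmrs, features) {
  dmrs <- as.data.frame(dmrs)
  if (nrow(dmrs) == 0L) {
    out <- list(assignment = data.frame(),
                summary = data.frame(kind = FEATURE_KINDS, n = 0L,
                                     percent = NA_real_))
    attr(out, "empty") <- TRUE
    return(out)
  }
  gd <- dmr_granges(dmrs)
  te_bp <- overlap_bp(gd, features_granges(features[features$kind == "TE", ,
                                                    drop = FALSE]))
  gene_bp <- overlap_bp(gd, features_granges(
    features[features$kind == "gene", , drop = FALSE]))
  any_bp <- overlap_bp(gd, features_granges(
    features[features$kind %in% c("gene", "TE"), , drop = FALSE]))
  other_bp <- GenomicRanges::width(gd) - any_bp
  # column order encodes the tie-break: TE > gene > other
  kind <- FEATURE_KINDS[c(2L, 1L, 3L)][
    max.col(cbind(te_bp, gene_bp, other_bp), ties.method = "first")]
  assignment <- data.frame(chrom = dmrs$chrom, start = dmrs$start,
                           end = dmrs$end, te_bp = te_bp,
                           gene_bp = gene_bp, other_bp = other_bp,
                           kind = kind, stringsAsFactors = FALSE)
  n <- vapply(FEATURE_KINDS, function(k) sum(kind == k), integer(1))
  summary <- data.frame(kind = FEATURE_KINDS, n = as.integer(n),
                        percent = 100 * n / nrow(dmrs),
                        stringsAsFactors = FALSE)
  list(assignment = assignment, summary = summary)
}
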