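#' Call differential expression with the fold-change + Fisher rule
#'
#' Implements the two-part decision rule used for mutant versus wild-type
#' comparisons without biological replicates: a feature is called `up`
#' when the fold-change of normalized reads exceeds `fc_min` and a
#' two-sided Fisher exact test on the raw counts is significant at
#' `alpha`; `down` uses the mirrored rule (fold below `1/fc_min`).
#'
#' Normalization scales each sample's counts to the smaller of the two
#' library sizes. The Fisher test is applied to the 2x2 table
#' `(count, library - count)` across the two samples — raw counts only,
#' so the test stays exact. The pseudocount enters the fold-change
#' denominator/numerator only, never the test.
#'
#' @param counts Data frame with a `feature_id` column and one count
#'   column per sample (extra non-sample columns such as `kind` are
#'   carried through).
#' @param sample_a,sample_b Column names of the reference and test
#'   samples.
#' @param lib_sizes Optional named numeric vector of library totals; by
#'   default the column sums of the two samples.
#' @param fc_min Fold-change threshold (default 2, strict `>`).
#' @param alpha Fisher p-value threshold (default 0.01).
#' @param pseudocount Added to both normalized counts for the
#'   fold-change (default 0.5).
#' @return A `data.frame` per feature with raw and normalized counts,
#'   `fold_change`, `p` and `call` in `{up, down, unchanged}`.
#' @export
call_differential_expression <- function(counts, sample_a, sample_b,
                                         lib_sizes = NULL, fc_min = 2,
                                         alpha = 0.01, pseudocount = 0.5) {
  for (s in c(sample_a, sample_b)) {
    if (!s %in% names(counts)) stop_param("sample column '%s' not found", s)
  }
  ca <- counts[[sample_a]]
  cb <- counts[[sample_b]]
  assert_nonneg_int(c(ca, cb), "expression counts")
  lib_a <- if (!is.null(lib_sizes)) lib_sizes[[sample_a]] else sum(ca)
  lib_b <- if (!is.null(lib_sizes)) lib_sizes[[sample_b]] else sum(cb)
  if (is.null(lib_a) || is.null(lib_b) || lib_a <= 0 || lib_b <= 0) {
    stop_param("library sizes must be positive")
  }
  if (any(ca > lib_a) || any(cb > lib_b)) {
    stop_param("feature counts exceed the library total")
  }
  scale_to <- min(lib_a, lib_b)
  norm_a <- ca * scale_to / lib_a
  norm_b <- cb * scale_to / lib_b
  fold <- (norm_b + pseudocount) / (norm_a + pseudocount)
  p <- fisher_exact_two_sided(ca, lib_a - ca, cb, lib_b - cb)
  call <- rep("unchanged", length(ca))
  call[fold > fc_min & p < alpha] <- "up"
  call[fold < 1 / fc_min & p < alpha] <- "down"
  extra <- counts[, setdiff(names(counts),
                            c(sample_a, sample_b)), drop = FALSE]
  out <- data.frame(extra, count_a = ca, count_b = cb,
                    norm_a = norm_a, norm_b = norm_b,
                    fold_change = fold, p = p, call = call,
                    stringsAsFactors = FALSE)
  attr(out, "lib_sizes") <- c(a = lib_a, b = lib_b)
  out
}

#' Partition up-regulated targets into common and specific sets
#'
#' The set-algebra behind the two-mutant Venn diagrams of up-regulated
#' TEs and genes: features up in both mutants are "common", the rest
#' specific to one mutant. Outputs are sorted by feature id for
#' deterministic downstream files.
#'
#' @param up_a,up_b Character vectors of up-regulated feature ids.
#' @return A list with sorted `common`, `specific_a`, `specific_b`.
#' @export
partition_targets <- function(up_a, up_b) {
  list(common = sort(intersect(up_a, up_b)),
       specific_a = sort(setdiff(up_a, up_b)),
       specific_b = sort(setdiff(up_b, up_a)))
}

#' Enrichment of a common target set
#'
#' Hypergeometric upper-tail test that the overlap between two
#' up-regulated sets is larger than expected when drawing from a
#' universe of `universe` features. Thin wrapper over
#' [hypergeometric_upper_tail()] so the DMR and expression enrichment
#' share one implementation.
#'
#' @param n_common Observed common features.
#' @param n_up_a,n_up_b Sizes of the two up-regulated sets.
#' @param universe Number of features in the tested universe.
#' @return Upper-tail p-value.
#' @export
set_enrichment <- function(n_common, n_up_a, n_up_b, universe) {
  hypergeometric_upper_tail(n_common, n_up_a, n_up_b, universe)
}
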