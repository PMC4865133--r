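#' Extract 24-nt siRNA counts from a length-stratified table
#'
#' Small-RNA counts arrive stratified by read length (one row per
#' feature, genotype and length). Only the 24-nt stratum — the
#' heterochromatic siRNA class that guides RdDM — is used for
#' profiling. Features without a 24-nt row get 0; a table with no 24-nt
#' stratum at all is an error (wrong input, not an empty class).
#'
#' @param sirna_counts Data frame with columns `feature_id`,
#'   `read_length`, `count` (a `genotype` column, if present, is kept as
#'   a grouping variable).
#' @param feature_ids Optional ids to report (defaults to those present).
#' @return A `data.table` with `feature_id` (and `genotype` if present)
#'   and the 24-nt `count`.
#' @export
count_24nt_reads <- function(sirna_counts, feature_ids = NULL) {
  dt <- data.table::as.data.table(sirna_counts)
  if (!any(dt$read_length == 24L)) {
    stop_param("no 24-nt stratum in the small-RNA count table")
  }
  by_cols <- intersect(c("feature_id", "genotype"), names(dt))
  agg <- dt[read_length == 24L, list(count = sum(count)), by = by_cols]
  if (!is.null(feature_ids)) {
    if ("genotype" %in% by_cols) {
      base <- data.table::CJ(feature_id = feature_ids,
                             genotype = unique(dt$genotype))
    } else {
      base <- data.table::data.table(feature_id = feature_ids)
    }
    agg <- merge(base, agg, by = by_cols, all.x = TRUE)
    agg[is.na(count), count := 0L]
  }
  agg[]
}

#' Reads per ten million (RPTM)
#'
#' Normalizes a small-RNA read count by the total reads of its library,
#' scaled to ten million: `count * 1e7 / library_total`.
#'
#' @param count Read count(s).
#' @param library_total Total reads of the small-RNA library.
#' @return Normalized abundance on the RPTM scale.
#' @export
rptm <- function(count, library_total) {
  if (any(is.na(library_total)) || any(library_total <= 0)) {
    stop_param("library_total must be positive")
  }
  count * 1e7 / library_total
}

#' Mutant/wild-type siRNA abundance fold change
#'
#' `(rptm_mut + c1) / (rptm_wt + c1)` with a pseudocount on the RPTM
#' scale. A feature is Pol IV-dependent when its fold change in the Pol
#' IV mutant (nrpd1) falls below the dependence cutoff, and Pol
#' V-independent when its fold change in the Pol V mutant (nrpe1) stays
#' at or above it.
#'
#' @param rptm_wt,rptm_mut Wild-type and mutant RPTM values.
#' @param pseudocount Pseudocount in RPTM units (default 1).
#' @return Fold change(s).
#' @export
dependence_fold_change <- function(rptm_wt, rptm_mut, pseudocount = 1) {
  (rptm_mut + pseudocount) / (rptm_wt + pseudocount)
}

#' Profile 24-nt siRNA abundance and polymerase dependence
#'
#' Computes per-feature 24-nt RPTM for the wild type and each mutant,
#' mutant/WT fold changes, and dependence labels: `dependent_<mut>` is
#' `TRUE` when the fold change drops below `dependence_cutoff`. When the
#' mutants include `nrpd1`/`nrpe1`, convenience columns
#' `pol_iv_dependent` and `pol_v_independent` are added. Features whose
#' wild-type abundance is below `min_wt_rptm` are flagged uninformative
#' (`informative = FALSE`) and their labels set to `NA`.
#'
#' The numeric dependence cutoff is not part of the published
#' procedure, which reports fold changes graphically; it is therefore an
#' explicit, echoed parameter (default 0.5).
#'
#' @param sirna_counts Length-stratified count table with columns
#'   `feature_id`, `genotype`, `read_length`, `count`.
#' @param lib_totals Named numeric vector of library totals per
#'   genotype.
#' @param wt Wild-type genotype label (default `"WT"`).
#' @param mutants Mutant genotype labels (default
#'   `c("nrpd1", "nrpe1")`).
#' @param dependence_cutoff Fold-change cutoff (default 0.5).
#' @param pseudocount RPTM pseudocount for fold changes (default 1).
#' @param min_wt_rptm Minimum wild-type RPTM for an informative call
#'   (default 5).
#' @return A `data.table` with `rptm_*`, `fold_*`, `dependent_*`,
#'   `informative` and, when applicable, the Pol IV / Pol V columns.
#' @export
sirna_profile <- function(sirna_counts, lib_totals, wt = "WT",
                          mutants = c("nrpd1", "nrpe1"),
                          dependence_cutoff = 0.5, pseudocount = 1,
                          min_wt_rptm = 5) {
  genos <- c(wt, mutants)
  missing_lib <- setdiff(genos, names(lib_totals))
  if (length(missing_lib)) {
    stop_param("no library total for genotype(s): %s",
               paste(missing_lib, collapse = ", "))
  }
  dt <- data.table::as.data.table(sirna_counts)
  ids <- sort(unique(dt$feature_id))
  c24 <- count_24nt_reads(dt[genotype %in% genos], feature_ids = ids)
  wide <- data.table::dcast(c24, feature_id ~ genotype,
                            value.var = "count", fill = 0L)
  out <- data.table::data.table(feature_id = wide$feature_id)
  for (g in genos) {
    cnt <- if (g %in% names(wide)) wide[[g]] else 0L
    out[, (paste0("rptm_", g)) := rptm(cnt, lib_totals[[g]])]
  }
  out[, informative := out[[paste0("rptm_", wt)]] >= min_wt_rptm]
  for (g in mutants) {
    f <- dependence_fold_change(out[[paste0("rptm_", wt)]],
                                out[[paste0("rptm_", g)]], pseudocount)
    out[, (paste0("fold_", g)) := f]
    dep <- ifelse(out$informative, f < dependence_cutoff, NA)
    out[, (paste0("dependent_", g)) := dep]
  }
  if ("nrpd1" %in% mutants) {
    out[, pol_iv_dependent := out$dependent_nrpd1]
  }
  if ("nrpe1" %in% mutants) {
    out[, pol_v_independent := !out$dependent_nrpe1]
  }
  data.table::setattr(out, "params",
                      list(dependence_cutoff = dependence_cutoff,
                           pseudocount = pseudocount,
                           min_wt_rptm = min_wt_rptm, wt = wt,
                           mutants = mutants))
  out[]
}
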