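#' Read a gene/TE annotation from GFF3 or BED
#'
#' Loads genomic features and normalizes them to the package's internal
#' representation: a data frame with 1-based closed coordinates and a
#' `kind` column in `{gene, TE, other}`.
#'
#' For GFF3 the kind is inferred from the type column: `gene` maps to
#' gene, any type starting with `transposable_element` maps to TE, and
#' everything else to other. For BED (0-based half-open on disk,
#' converted on read) the kind is inferred from the name column via
#' `te_name_regex`, with non-matching names treated as genes.
#'
#' @param path Annotation file.
#' @param dialect `"auto"` (by extension), `"gff3"` or `"bed"`.
#' @param te_name_regex Regular expression applied to BED names to flag
#'   transposable elements (default `"TE"`, which matches TAIR-style ids
#'   such as `AT1TE45510`).
#' @param rename_chroms Optional chromosome rename map, as in
#'   [read_cytosine_report()].
#' @return A `data.frame` with columns `feature_id`, `chrom`, `start`,
#'   `end` (1-based closed), `strand` and `kind`.
#' @export
read_features <- function(path, dialect = c("auto", "gff3", "bed"),
                          te_name_regex = "TE", rename_chroms = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3"
  }
  gr <- rtracklayer::import(path, format = if (dialect == "bed") "bed" else "gff3")
  if (length(gr) == 0L) {
    return(data.frame(feature_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), kind = character(),
                      stringsAsFactors = FALSE))
  }
  md <- S4Vectors::mcols(gr)
  if (dialect == "gff3") {
    type <- as.character(md$type)
    kind <- ifelse(type == "gene", "gene",
                   ifelse(startsWith(type, "transposable_element"), "TE",
                          "other"))
    id <- if (!is.null(md$ID)) as.character(md$ID) else NA_character_
    if (!is.null(md$Name)) id <- ifelse(is.na(id), as.character(md$Name), id)
    id[is.na(id)] <- paste0(type[is.na(id)], "_", which(is.na(id)))
  } else {
    id <- if (!is.null(md$name)) as.character(md$name) else
      paste0("feature_", seq_along(gr))
    kind <- ifelse(grepl(te_name_regex, id), "TE", "gene")
  }
  out <- data.frame(
    feature_id = id,
    chrom = apply_rename(as.character(GenomicRanges::seqnames(gr)),
                         rename_chroms),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    kind = kind,
    stringsAsFactors = FALSE)
  out$strand[out$strand == "*"] <- "."
  if (any(out$start > out$end)) {
    stop_param("invalid feature interval in '%s': start > end", path)
  }
  if (anyDuplicated(out$feature_id)) {
    stop_param("duplicate feature_id in '%s': %s", path,
               out$feature_id[duplicated(out$feature_id)][1])
  }
  out
}

#' Write an annotation as GFF3
#'
#' Genes are written with type `gene`, TEs with type
#' `transposable_element`, and other features with type
#' `uncharacterized_region`; coordinates are 1-based inclusive as the
#' format requires. Round-trips through [read_features()].
#'
#' @param features Feature data frame (see [read_features()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_features_gff3 <- function(features, path) {
  type <- c(gene = "gene", TE = "transposable_element",
            other = "uncharacterized_region")[features$kind]
  lines <- sprintf("%s\trddmr\t%s\t%d\t%d\t.\t%s\t.\tID=%s",
                   features$chrom, type, features$start, features$end,
                   ifelse(features$strand %in% c("+", "-"),
                          features$strand, "."),
                   features$feature_id)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}
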