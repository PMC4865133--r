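#' Read a per-cytosine methylation report
#'
#' Parses the tab-separated cytosine report dialect written by Bismark's
#' methylation extractor (CX report): one row per cytosine with columns
#' chromosome, 1-based position, strand, methylated read count,
#' unmethylated read count and sequence context (`CG`, `CHG` or `CHH`;
#' H is A, T or C). An optional seventh trinucleotide column is ignored,
#' as are `#`-prefixed comment lines.
#'
#' No strand collapsing is performed: symmetric CG positions on opposite
#' strands stay separate rows, and pooling decisions are left to the
#' consumers (windowing and feature-level summaries pool read counts).
#'
#' @param path Path to the tab-separated report.
#' @param rename_chroms Optional named character vector mapping chromosome
#'   names in the file to the names used internally (e.g.
#'   `c("1" = "Chr1")`). Chromosome comparison elsewhere in the package is
#'   exact string match; use this map rather than relying on aliasing.
#' @return A `data.frame` with columns `chrom`, `pos` (1-based), `strand`,
#'   `context`, `count_meth`, `count_unmeth`, in file order.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("Chr1\t1001\t+\t8\t2\tCG\tCGT",
#'              "Chr1\t1005\t-\t0\t7\tCHH"), f)
#' read_cytosine_report(f)
#' @export
read_cytosine_report <- function(path, rename_chroms = NULL) {
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  empty <- data.frame(
    chrom = character(), pos = integer(), strand = character(),
    context = character(), count_meth = integer(),
    count_unmeth = integer(), stringsAsFactors = FALSE)
  if (length(lines) == 0L) return(empty)

  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf < 6L)
  if (length(bad)) {
    stop_param("malformed line %d in '%s': expected >= 6 tab-separated fields, found %d",
               lineno[bad[1]], path, nf[bad[1]])
  }
  field <- function(i) vapply(parts, `[[`, character(1), i)
  chrom <- field(1L)
  pos <- suppressWarnings(as.integer(field(2L)))
  strand <- field(3L)
  count_meth <- suppressWarnings(as.integer(field(4L)))
  count_unmeth <- suppressWarnings(as.integer(field(5L)))
  context <- field(6L)

  bad <- which(is.na(pos) | is.na(count_meth) | is.na(count_unmeth))
  if (length(bad)) {
    stop_param("malformed line %d in '%s': non-integer position or count",
               lineno[bad[1]], path)
  }
  bad <- which(count_meth < 0L | count_unmeth < 0L)
  if (length(bad)) {
    stop_param("invalid line %d in '%s': negative read count",
               lineno[bad[1]], path)
  }
  bad <- which(!strand %in% c("+", "-"))
  if (length(bad)) {
    stop_param("invalid line %d in '%s': strand must be '+' or '-', found '%s'",
               lineno[bad[1]], path, strand[bad[1]])
  }
  bad <- which(!context %in% CONTEXTS)
  if (length(bad)) {
    stop_param("invalid line %d in '%s': unknown context '%s' (expected CG, CHG or CHH)",
               lineno[bad[1]], path, context[bad[1]])
  }
  chrom <- apply_rename(chrom, rename_chroms)
  dup <- which(duplicated(paste(chrom, pos, strand, sep = "\r")))
  if (length(dup)) {
    stop_param("invalid line %d in '%s': duplicate (chrom, pos, strand) = (%s, %d, %s)",
               lineno[dup[1]], path, chrom[dup[1]], pos[dup[1]], strand[dup[1]])
  }
  data.frame(chrom = chrom, pos = pos, strand = strand, context = context,
             count_meth = count_meth, count_unmeth = count_unmeth,
             stringsAsFactors = FALSE)
}

#' Write a per-cytosine methylation report
#'
#' Inverse of [read_cytosine_report()]; used mainly by the synthetic-data
#' generator to materialize simulated methylomes on disk.
#'
#' @param sites Data frame with columns `chrom`, `pos`, `strand`,
#'   `context`, `count_meth`, `count_unmeth`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cytosine_report <- function(sites, path) {
  df <- sites[, c("chrom", "pos", "strand", "count_meth", "count_unmeth",
                  "context")]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
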