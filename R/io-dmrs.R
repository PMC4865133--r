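#' Write DMRs as BED6+ TSV
#'
#' Emits one row per differentially methylated region in an extended BED
#' dialect: `chrom`, `start` (0-based), `end` (half-open), `name`
#' (`hypo_1`, `hyper_2`, ...), `score` (-log10 of the minimum window
#' p-value, capped at 300), `strand` (always `.`), then `delta_total`
#' (pooled-count methylation difference over the region), `n_windows`,
#' `direction` and `p_min`. Rows are sorted by (chrom, start); a single
#' `#`-prefixed header line names the columns. [read_dmrs()] is the exact
#' inverse.
#'
#' @param dmrs DMR data frame as produced by [merge_windows()] or
#'   [call_dmrs()] (1-based closed coordinates internally).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dmrs <- function(dmrs, path) {
  header <- paste0("#", paste(
    c("chrom", "start", "end", "name", "score", "strand",
      "delta_total", "n_windows", "direction", "p_min"), collapse = "\t"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  if (nrow(dmrs) == 0L) return(invisible(path))
  d <- as.data.frame(dmrs)[order(dmrs$chrom, dmrs$start), , drop = FALSE]
  score <- pmin(-log10(pmax(d$p_min, 0)), 300)
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t.\t%s\t%d\t%s\t%s",
                   d$chrom, d$start - 1L, d$end,
                   paste0(d$direction, "_", seq_len(nrow(d))),
                   trimws(formatC(score, digits = 6, format = "g")),
                   trimws(formatC(d$delta_total, digits = 15,
                                  format = "g")),
                   as.integer(d$n_windows), d$direction,
                   trimws(formatC(d$p_min, digits = 15, format = "g")))
  writeLines(lines, con)
  invisible(path)
}

#' Read DMRs written by [write_dmrs()]
#'
#' @param path Path to a DMR BED6+ file.
#' @return DMR data frame with 1-based closed `start`/`end`, `direction`,
#'   `n_windows`, `delta_total`, `p_min` and the stored `name`.
#' @export
read_dmrs <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), direction = character(),
                      n_windows = integer(), delta_total = numeric(),
                      p_min = numeric(), name = character(),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 10L)) {
    stop_param("malformed DMR file '%s': expected 10 columns", path)
  }
  field <- function(i) vapply(parts, `[[`, character(1), i)
  data.frame(
    chrom = field(1), start = as.integer(field(2)) + 1L,
    end = as.integer(field(3)), direction = field(9),
    n_windows = as.integer(field(8)),
    delta_total = as.numeric(field(7)), p_min = as.numeric(field(10)),
    name = field(4), stringsAsFactors = FALSE)
}
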