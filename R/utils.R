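# Internal helpers shared across modules.

CONTEXTS <- c("CG", "CHG", "CHH")
FEATURE_KINDS <- c("gene", "TE", "other")

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_param <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_nonneg_int <- function(x, what) {
  if (any(is.na(x)) || any(x < 0) || any(x != floor(x))) {
    stop_param("%s must be non-negative integers", what)
  }
}

# Deterministic 32-bit sub-seed from a base seed and a stage tag, so every
# generator is a pure function of (config, tag) and independent stages do
# not share RNG streams.
derive_seed <- function(seed, tag) {
  h <- 0
  for (ch in utf8ToInt(tag)) h <- (h * 31 + ch) %% 1000003L
  as.integer((as.numeric(seed) * 2654435
              + h * 97 + 12345) %% 2147483647)
}

# Evaluate `expr` under a local RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# data.frame of features -> GRanges (1-based closed, as stored).
features_granges <- function(features) {
  GenomicRanges::GRanges(
    seqnames = features$chrom,
    ranges = IRanges::IRanges(start = features$start, end = features$end),
    strand = ifelse(features$strand %in% c("+", "-"), features$strand, "*")
  )
}

dmr_granges <- function(dmrs) {
  GenomicRanges::GRanges(
    seqnames = dmrs$chrom,
    ranges = IRanges::IRanges(start = dmrs$start, end = dmrs$end)
  )
}

# Per-query base pairs covered by `subject` (GRanges), ignoring strand.
overlap_bp <- function(query, subject) {
  out <- numeric(length(query))
  if (length(subject) == 0L || length(query) == 0L) return(out)
  subject <- GenomicRanges::reduce(subject, ignore.strand = TRUE)
  h <- GenomicRanges::findOverlaps(query, subject, ignore.strand = TRUE)
  if (length(h) == 0L) return(out)
  w <- GenomicRanges::width(GenomicRanges::pintersect(
    query[S4Vectors::queryHits(h)], subject[S4Vectors::subjectHits(h)],
    ignore.strand = TRUE))
  agg <- tapply(w, S4Vectors::queryHits(h), sum)
  out[as.integer(names(agg))] <- as.numeric(agg)
  out
}

apply_rename <- function(x, rename) {
  if (is.null(rename)) return(x)
  hit <- x %in% names(rename)
  x[hit] <- unname(rename[x[hit]])
  x
}
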