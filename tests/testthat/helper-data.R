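# Small in-code fixtures shared across test files.

make_sites <- function(pos, context, m, u, chrom = "Chr1", strand = "+") {
  n <- length(pos)
  data.frame(chrom = rep_len(chrom, n), pos = pos,
             strand = rep_len(strand, n), context = rep_len(context, n),
             count_meth = m, count_unmeth = u, stringsAsFactors = FALSE)
}

make_features <- function(start, end, kind, strand = "+", chrom = "Chr1",
                          id = NULL) {
  n <- length(start)
  data.frame(feature_id = id %||% sprintf("feat_%02d", seq_len(n)),
             chrom = rep_len(chrom, n), start = start, end = end,
             strand = rep_len(strand, n), kind = rep_len(kind, n),
             stringsAsFactors = FALSE)
}

make_dmrs <- function(start, end, direction = "hypo", chrom = "Chr1",
                      p_min = 1e-6, delta_total = -0.3) {
  n <- length(start)
  data.frame(chrom = rep_len(chrom, n), start = start, end = end,
             direction = rep_len(direction, n),
             n_windows = rep_len(1L, n),
             delta_total = rep_len(delta_total, n),
             p_min = rep_len(p_min, n), stringsAsFactors = FALSE)
}

# Differential-window rows with the columns merge_windows() consumes.
make_diff_windows <- function(start, end, direction, chrom = "Chr1",
                              m_a = 40L, u_a = 10L, m_b = 10L, u_b = 40L,
                              p = 1e-6) {
  n <- length(start)
  hypo <- rep_len(direction == "hypo", n)
  m_a <- rep_len(m_a, n); u_a <- rep_len(u_a, n)
  m_b <- rep_len(m_b, n); u_b <- rep_len(u_b, n)
  data.frame(chrom = rep_len(chrom, n), start = start, end = end,
             m_a = ifelse(hypo, m_a, m_b), u_a = ifelse(hypo, u_a, u_b),
             m_b = ifelse(hypo, m_b, m_a), u_b = ifelse(hypo, u_b, u_a),
             p = rep_len(p, n), direction = rep_len(direction, n),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
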