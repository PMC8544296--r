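# Independent brute-force oracles used across test files. These deliberately
# re-derive results from first principles (per-base tables, position-by-
# position scans, enumeration) and never call the package code paths they
# check.

# Per-base region lookup table for one transcript: a character vector of
# length L with one label per base.
oracle_region_table <- function(length, cds_start, cds_end) {
  rep(c("utr5", "cds", "utr3"),
      c(cds_start, cds_end - cds_start, length - cds_end))
}

# Brute-force uORF scan: test every position p < cds_start for "ATG", then
# walk codon by codon through the whole transcript for the first stop.
oracle_find_uorfs <- function(seq, cds_start) {
  seq <- toupper(chartr("Uu", "Tt", seq))
  L <- nchar(seq)
  codon_at <- function(p) substr(seq, p + 1L, p + 3L)  # p is 0-based
  out <- list()
  for (p in seq_len(cds_start) - 1L) {
    if (p + 3L > L || codon_at(p) != "ATG") next
    stop_pos <- NA_integer_
    q <- p + 3L
    while (q + 3L <= L) {
      if (codon_at(q) %in% c("TAA", "TAG", "TGA")) { stop_pos <- q + 3L; break }
      q <- q + 3L
    }
    out[[length(out) + 1L]] <- data.frame(
      uaug_pos = p, stop_pos = stop_pos,
      overlaps_cds = is.na(stop_pos) || stop_pos > cds_start)
  }
  if (!length(out))
    return(data.frame(uaug_pos = integer(), stop_pos = integer(),
                      overlaps_cds = logical()))
  do.call(rbind, out)
}

# Exhaustive hypergeometric upper tail P(X >= k) by direct summation of the
# probability mass function written out in binomial coefficients.
oracle_hyper_upper <- function(k, N, K, n) {
  j <- k:min(n, K)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# AUROC by its definition: probability a positive outranks a negative
# (ties count 1/2).
oracle_auroc <- function(pos, neg) {
  cmp <- outer(pos, neg, "-")
  mean((cmp > 0) + 0.5 * (cmp == 0))
}

# Random transcript-model table (no sequences) for coordinate tests.
random_models <- function(n, seed) {
  withr::with_seed(seed, {
    utr5 <- sample(0:150, n, replace = TRUE)
    cds <- 3L * sample(20:200, n, replace = TRUE)
    utr3 <- sample(0:300, n, replace = TRUE)
    validate_transcript_models(data.table::data.table(
      transcript_id = sprintf("T%03d", seq_len(n)),
      gene_id = sprintf("g%03d", seq_len(n)),
      length = utr5 + cds + utr3, cds_start = utr5, cds_end = utr5 + cds))
  })
}

# Random nucleotide string.
random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}
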