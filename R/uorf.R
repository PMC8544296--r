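#' Detect upstream open reading frames
#'
#' Scans the 5'UTR of a transcript (positions `< cds_start`) for every AUG
#' and pairs each with the first in-frame stop codon (UAA/UAG/UGA) found
#' scanning 3' through the *whole* transcript, so uORFs may extend into and
#' overlap the CDS. Near-cognate (non-AUG) starts are not considered.
#' Input sequences may be DNA or RNA; U and T are equivalent.
#'
#' @param models transcript-model table with attached sequences
#'   ([attach_sequences()]).
#' @param transcript_ids optional subset of transcripts to scan.
#' @return `data.table` sorted by transcript and `uaug_pos`:
#'   `transcript_id`, `uaug_pos` (0-based offset of the A of the AUG),
#'   `stop_pos` (0-based offset one past the stop codon; `NA` when no
#'   in-frame stop exists anywhere in the transcript), `length` (nt,
#'   start..stop inclusive; `NA` without a stop), `overlaps_cds` (stop beyond
#'   `cds_start`, or no stop), `kozak` (strong/adequate/weak), and
#'   `cap_distance` (nt from the transcript 5' end, equal to `uaug_pos`).
#'   Transcripts with `cds_start == 0` (no 5'UTR) yield no rows.
#' @export
find_uorfs <- function(models, transcript_ids = NULL) {
  models <- as.data.table(models)
  if (!is.null(transcript_ids))
    models <- models[transcript_id %in% transcript_ids]
  if (any(is.na(models$sequence)))
    stop("sequences required; call attach_sequences() first")
  res <- vector("list", nrow(models))
  for (i in seq_len(nrow(models))) {
    res[[i]] <- find_uorfs_one(models$transcript_id[i],
                               models$sequence[i],
                               models$cds_start[i])
  }
  out <- rbindlist(res)
  if (nrow(out) == 0L)
    return(data.table(transcript_id = character(), uaug_pos = integer(),
                      stop_pos = integer(), length = integer(),
                      overlaps_cds = logical(), kozak = character(),
                      cap_distance = integer()))
  setorder(out, transcript_id, uaug_pos)
  out[]
}

find_uorfs_one <- function(tid, seq, cds_start) {
  seq <- normalize_seq(seq)
  if (cds_start == 0L) return(NULL)
  bad <- gregexpr("[^ACGT]", seq)[[1L]]
  if (bad[1L] != -1L)
    warning("transcript ", tid, ": non-ACGTU characters; affected frames skipped")
  # scan the whole sequence so AUGs whose codon spans the 5'UTR/CDS boundary
  # (uaug_pos < cds_start <= uaug_pos+2) are still found
  aug <- gregexpr("(?=ATG)", seq, perl = TRUE)[[1L]]
  if (aug[1L] == -1L) return(NULL)
  aug0 <- as.integer(aug) - 1L                       # 0-based A positions
  aug0 <- aug0[aug0 < cds_start]
  if (!length(aug0)) return(NULL)
  # all (possibly overlapping) stop-codon positions in the whole transcript
  st <- gregexpr("(?=TAA|TAG|TGA)", seq, perl = TRUE)[[1L]]
  st0 <- if (st[1L] == -1L) integer() else as.integer(st) - 1L
  rows <- lapply(aug0, function(p) {
    cand <- st0[st0 >= p + 3L & (st0 - p) %% 3L == 0L]
    # a codon containing ambiguous characters must not count as start/stop;
    # gregexpr on ACGT patterns already guarantees clean matches
    sp <- if (length(cand)) min(cand) + 3L else NA_integer_
    data.table(transcript_id = tid, uaug_pos = p, stop_pos = sp,
               length = if (is.na(sp)) NA_integer_ else sp - p,
               overlaps_cds = is.na(sp) || sp > cds_start,
               kozak = kozak_score(seq, p),
               cap_distance = p)
  })
  rbindlist(rows)
}

normalize_seq <- function(seq) {
  chartr("u", "t", toupper(chartr("U", "T", seq)))
}

#' Kozak context class of an AUG
#'
#' Classical two-position rule: the initiation context is `strong` when the
#' -3 position (3 nt upstream of the A of the AUG) is a purine (A/G) *and*
#' the +4 position (the base immediately after the AUG) is G; `adequate` when
#' exactly one condition holds; `weak` when neither does. A flanking position
#' that does not exist (AUG within 3 nt of the cap, or at the transcript end)
#' counts as not satisfying its condition.
#'
#' @param sequence transcript (or 5'UTR) sequence, DNA or RNA.
#' @param aug_pos 0-based position of the A of the AUG (vectorised).
#' @return character vector: `"strong"`, `"adequate"` or `"weak"`.
#' @export
kozak_score <- function(sequence, aug_pos) {
  seq <- normalize_seq(sequence)
  if (length(seq) == 1L && length(aug_pos) > 1L)
    seq <- rep(seq, length(aug_pos))
  m3 <- ifelse(aug_pos >= 3L, substr(seq, aug_pos - 2L, aug_pos - 2L), "")
  p4 <- substr(seq, aug_pos + 4L, aug_pos + 4L)     # may be "" past the end
  ok3 <- m3 %in% c("A", "G")
  ok4 <- p4 == "G"
  fifelse(ok3 & ok4, "strong", fifelse(ok3 | ok4, "adequate", "weak"))
}

#' Cap-to-uORF distance
#'
#' Distance in nt from the transcript 5' end (position 0, the cap) to the
#' uAUG. Greater distance gives the scanning ribosome a longer loading zone
#' and, with a strong context, stronger repression of the main ORF.
#'
#' @param uorfs table from [find_uorfs()] (or anything with `uaug_pos`).
#' @export
cap_distance <- function(uorfs) {
  as.integer(as.data.table(uorfs)$uaug_pos)
}

#' CDS:5'UTR ribosome density shift score
#'
#' Per transcript, the ratio of CDS RPFs to 5'UTR RPFs is computed in each
#' condition with a pseudocount, and the shift is
#' `log2(ratio_treat / ratio_ctrl)`. A positive shift means ribosome density
#' moved out of the 5'UTR into the CDS under treatment - the signature of
#' uORF bypass and translational induction of the main ORF.
#'
#' @param counts_ctrl,counts_treat region-count tables (rpf library) for the
#'   two conditions; replicates should be pooled beforehand (or pass
#'   per-sample tables summed with [pool_region_counts()]).
#' @param pseudocount added to both numerator and denominator (default 1),
#'   keeping ratios finite when a region has zero reads.
#' @return `data.table`: `transcript_id`, `ratio_ctrl`, `ratio_treat`,
#'   `log2_shift`. Transcripts present in only one condition are skipped
#'   with a notice.
#' @export
shift_score <- function(counts_ctrl, counts_treat, pseudocount = 1) {
  a <- pool_region_counts(counts_ctrl)
  b <- pool_region_counts(counts_treat)
  common <- intersect(a$transcript_id, b$transcript_id)
  n_skip <- length(union(a$transcript_id, b$transcript_id)) - length(common)
  if (n_skip > 0L)
    message(n_skip, " transcript(s) absent in one condition skipped")
  a <- a[transcript_id %in% common]
  b <- b[transcript_id %in% common]
  out <- a[, .(transcript_id,
               ratio_ctrl = (n_cds + pseudocount) / (n_utr5 + pseudocount))]
  out <- out[b[, .(transcript_id,
                   ratio_treat = (n_cds + pseudocount) / (n_utr5 + pseudocount))],
             on = "transcript_id"]
  out[, log2_shift := log2(ratio_treat) - log2(ratio_ctrl)]
  setorder(out, transcript_id)
  out[]
}

#' Pool RPF region counts across samples
#'
#' Sums region counts per transcript over all samples present in the table
#' (use after subsetting to one condition's replicates).
#' @param rc region-count table; non-rpf rows are dropped.
#' @export
pool_region_counts <- function(rc) {
  rc <- as.data.table(rc)
  if ("library" %in% names(rc)) rc <- rc[library == "rpf"]
  rc[, .(n_utr5 = sum(n_utr5), n_cds = sum(n_cds), n_utr3 = sum(n_utr3),
         n_total = sum(n_utr5) + sum(n_cds) + sum(n_utr3)),
     by = transcript_id]
}
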