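#' Read transcript-space alignments
#'
#' Alignments are read placements in transcript coordinates (0-based start).
#' Two formats are supported: a minimal TSV with columns
#' `transcript_id`, `start`, `read_length` (extra columns ignored), and SAM
#' with the transcript as reference sequence (POS is converted from 1-based;
#' the read length is the query width, falling back to the reference span of
#' the CIGAR when no sequence is stored). Unmapped records are skipped.
#'
#' @param path alignment file (`.tsv`/`.txt` or `.sam`).
#' @param sample_id sample label attached to every read.
#' @param library `"rpf"` or `"rna"`.
#' @param format `"auto"` (by extension), `"tsv"` or `"sam"`.
#' @return `data.table` with columns `transcript_id`, `start`, `read_length`,
#'   `sample_id`, `library`.
#' @export
read_alignments <- function(path, sample_id, library = c("rpf", "rna"),
                            format = c("auto", "tsv", "sam")) {
  library <- match.arg(library)
  format <- match.arg(format)
  if (!file.exists(path)) stop("alignment file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.sam$", path, ignore.case = TRUE)) "sam" else "tsv"
  aln <- if (format == "sam") read_alignments_sam(path) else read_alignments_tsv(path)
  aln[, `:=`(sample_id = sample_id, library = library)]
  validate_alignments(aln)
}

read_alignments_tsv <- function(path) {
  dt <- fread(path, sep = "\t")
  req <- c("transcript_id", "start", "read_length")
  if (!all(req %in% names(dt))) {
    if (ncol(dt) >= 3L && !"transcript_id" %in% names(dt)) {
      # headerless fixture: first three columns in canonical order
      dt <- fread(path, sep = "\t", header = FALSE)
      setnames(dt, 1:3, req)
    } else stop("alignment TSV needs columns: ", paste(req, collapse = ", "))
  }
  dt[, .(transcript_id = as.character(transcript_id),
         start = as.integer(start), read_length = as.integer(read_length))]
}

read_alignments_sam <- function(path) {
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
  p <- Rsamtools::ScanBamParam(
    what = c("rname", "pos", "qwidth", "cigar"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
  x <- Rsamtools::scanBam(bam, param = p)[[1L]]
  len <- x$qwidth
  no_q <- is.na(len)
  if (any(no_q)) len[no_q] <- cigar_ref_width(x$cigar[no_q])
  data.table(transcript_id = as.character(x$rname),
             start = as.integer(x$pos) - 1L,
             read_length = as.integer(len))
}

# reference-space width of simple CIGARs (sum of M/D/N/=/X op lengths)
cigar_ref_width <- function(cigar) {
  vapply(cigar, function(cg) {
    ops <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1L]]
    consume <- grepl("[MDN=X]$", ops)
    sum(as.integer(sub("[A-Z=]$", "", ops[consume])))
  }, integer(1), USE.NAMES = FALSE)
}

validate_alignments <- function(aln) {
  aln <- as.data.table(aln)
  req <- c("transcript_id", "start", "read_length", "sample_id", "library")
  miss <- setdiff(req, names(aln))
  if (length(miss)) stop("missing alignment columns: ", paste(miss, collapse = ", "))
  if (nrow(aln) && any(aln$start < 0L)) stop("negative alignment start")
  if (nrow(aln) && any(aln$read_length <= 0L)) stop("non-positive read length")
  bad_lib <- setdiff(unique(aln$library), c("rpf", "rna"))
  if (length(bad_lib)) stop("unknown library type: ", paste(bad_lib, collapse = ", "))
  setcolorder(aln, req)
  aln[]
}

#' Write alignments as TSV
#' @param aln alignment table.
#' @param path output file.
#' @export
write_alignments_tsv <- function(aln, path) {
  fwrite(as.data.table(aln)[, .(transcript_id, start, read_length)],
         path, sep = "\t")
  invisible(path)
}

#' Write alignments as SAM
#'
#' Emits a minimal valid SAM in transcript space: one `@SQ` line per
#' transcript, mapped single-end records with CIGAR `<len>M` and the read
#' sequence taken from the transcript (or N's when no sequence is attached).
#'
#' @param aln alignment table (one sample/library).
#' @param models transcript-model table (for `@SQ` lengths and sequences).
#' @param path output file.
#' @export
write_alignments_sam <- function(aln, models, path) {
  aln <- as.data.table(aln)
  models <- as.data.table(models)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", models$transcript_id, models$length), con)
  if (nrow(aln)) {
    m <- match(aln$transcript_id, models$transcript_id)
    if (anyNA(m)) stop("alignment to unknown transcript")
    seqs <- models$sequence[m]
    read_seq <- ifelse(is.na(seqs),
                       strrep("N", aln$read_length),
                       substr(seqs, aln$start + 1L, aln$start + aln$read_length))
    rec <- sprintf("r%d\t0\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*",
                   seq_len(nrow(aln)), aln$transcript_id, aln$start + 1L,
                   aln$read_length, read_seq)
    writeLines(rec, con)
  }
  invisible(path)
}
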