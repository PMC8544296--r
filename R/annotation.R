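#' Read transcript models from BED12 or GTF
#'
#' Parses transcript annotation and converts every transcript to the single
#' coordinate convention used throughout the package: transcript-space,
#' 0-based, half-open. A transcript of length L is partitioned exactly into
#' 5'UTR `[0, cds_start)`, CDS `[cds_start, cds_end)` (stop codon included,
#' matching BED thick-interval practice) and 3'UTR `[cds_end, L)`; the 5'UTR
#' and/or 3'UTR may be empty.
#'
#' For BED12 the thickStart/thickEnd interval defines the CDS and is mapped
#' from genome to transcript coordinates through the block structure
#' (minus-strand transcripts are flipped so position 0 is the cap). BED names
#' of the form `"<transcript_id>|<gene_id>"` carry the gene assignment;
#' otherwise `gene_id == transcript_id`. For GTF, `exon` features define the
#' transcript body and `CDS` features the coding interval.
#'
#' @param path file path.
#' @param format `"bed12"` or `"gtf"`.
#' @return A `data.table` with one row per transcript: `transcript_id`,
#'   `gene_id`, `length`, `cds_start`, `cds_end`, `cds_frame_ok` (FALSE flags
#'   a CDS whose length is not a multiple of 3; the record is kept but
#'   flagged), and `sequence` (`NA` until [attach_sequences()] is called).
#'   Transcripts without an annotated CDS are dropped with a warning;
#'   duplicated transcript ids or a CDS outside the transcript are errors.
#' @export
read_annotation <- function(path, format = c("bed12", "gtf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  models <- switch(format,
    bed12 = read_annotation_bed12(path),
    gtf   = read_annotation_gtf(path)
  )
  validate_transcript_models(models)
}

read_annotation_bed12 <- function(path) {
  gr <- tryCatch(
    rtracklayer::import(path, format = "bed"),
    error = function(e) stop("malformed BED12 at ", path, ": ", conditionMessage(e))
  )
  if (length(gr) == 0L) stop("no records in ", path)
  if (is.null(gr$blocks)) {
    # plain BED (no blocks): treat as single-exon
    gr$blocks <- methods::as(S4Vectors::split(
      IRanges::IRanges(1L, BiocGenerics::width(gr)), seq_along(gr)), "IRangesList")
  }
  nm <- as.character(gr$name)
  if (anyNA(nm) || any(nm == "")) stop("BED12 records must be named (column 4)")
  tid <- sub("\\|.*$", "", nm)
  gid <- ifelse(grepl("|", nm, fixed = TRUE), sub("^[^|]*\\|", "", nm), tid)

  out <- vector("list", length(gr))
  chrom_start <- BiocGenerics::start(gr) - 1L   # back to 0-based
  strand <- as.character(BiocGenerics::strand(gr))
  thick <- gr$thick
  for (i in seq_along(gr)) {
    bl <- gr$blocks[[i]]
    # blocks are 1-based relative to chromStart -> 0-based genomic half-open
    ex_start <- chrom_start[i] + BiocGenerics::start(bl) - 1L
    ex_end <- chrom_start[i] + BiocGenerics::end(bl)
    tx_len <- sum(ex_end - ex_start)
    th_s <- BiocGenerics::start(thick)[i] - 1L   # 0-based
    th_e <- BiocGenerics::end(thick)[i]          # half-open
    if (th_e <= th_s) {
      out[[i]] <- NULL  # non-coding record
      next
    }
    cds <- genome_interval_to_tx(th_s, th_e, ex_start, ex_end, strand[i],
                                 transcript_id = tid[i])
    out[[i]] <- data.table(
      transcript_id = tid[i], gene_id = gid[i], length = as.integer(tx_len),
      cds_start = cds[1L], cds_end = cds[2L]
    )
  }
  dropped <- sum(vapply(out, is.null, logical(1)))
  if (dropped > 0L)
    warning(dropped, " non-coding record(s) (thickStart == thickEnd) dropped")
  models <- rbindlist(out)
  if (nrow(models) == 0L) stop("no coding transcripts in ", path)
  models
}

read_annotation_gtf <- function(path) {
  gr <- tryCatch(
    rtracklayer::import(path, format = "gtf"),
    error = function(e) stop("malformed GTF at ", path, ": ", conditionMessage(e))
  )
  ex <- gr[gr$type == "exon"]
  cds <- gr[gr$type == "CDS"]
  if (length(ex) == 0L) stop("no exon features in ", path)
  if (length(cds) == 0L) stop("no CDS features in ", path)
  ex_dt <- data.table(
    transcript_id = as.character(ex$transcript_id),
    gene_id = as.character(ex$gene_id),
    start = BiocGenerics::start(ex) - 1L, end = BiocGenerics::end(ex),
    strand = as.character(BiocGenerics::strand(ex))
  )
  cds_dt <- data.table(
    transcript_id = as.character(cds$transcript_id),
    start = BiocGenerics::start(cds) - 1L, end = BiocGenerics::end(cds)
  )
  setkey(ex_dt, transcript_id, start)
  cds_rng <- cds_dt[, .(cs = min(start), ce = max(end)), by = transcript_id]
  out <- ex_dt[, {
    tx <- .BY[[1L]]
    rng <- cds_rng[.(transcript_id = tx), on = "transcript_id"]
    if (is.na(rng$cs)) NULL else {
      cdsc <- genome_interval_to_tx(rng$cs, rng$ce, start, end, strand[1L],
                                    transcript_id = tx)
      list(gene_id = gene_id[1L], length = as.integer(sum(end - start)),
           cds_start = cdsc[1L], cds_end = cdsc[2L])
    }
  }, by = transcript_id]
  if (nrow(out) == 0L) stop("no transcripts with CDS in ", path)
  out
}

#' Map a genomic position to a transcript offset
#'
#' Both sides 0-based; exons must be sorted by genomic start, non-overlapping.
#' Minus-strand transcripts count from the genomic end (the cap).
#' @noRd
genome_pos_to_tx <- function(gpos, ex_start, ex_end, strand) {
  hit <- which(gpos >= ex_start & gpos < ex_end)
  if (length(hit) != 1L) return(NA_integer_)
  off_plus <- if (hit > 1L) sum(ex_end[seq_len(hit - 1L)] - ex_start[seq_len(hit - 1L)]) else 0L
  off_plus <- off_plus + (gpos - ex_start[hit])
  if (strand == "-") {
    total <- sum(ex_end - ex_start)
    as.integer(total - 1L - off_plus)
  } else as.integer(off_plus)
}

# Map a genomic half-open interval to a transcript-space half-open interval.
# Boundaries must fall inside exons (typical for a CDS thick interval).
genome_interval_to_tx <- function(gstart, gend, ex_start, ex_end, strand,
                                  transcript_id = "?") {
  o <- order(ex_start)
  ex_start <- ex_start[o]; ex_end <- ex_end[o]
  a <- genome_pos_to_tx(gstart, ex_start, ex_end, strand)       # first CDS base
  b <- genome_pos_to_tx(gend - 1L, ex_start, ex_end, strand)    # last CDS base
  if (is.na(a) || is.na(b))
    stop("CDS interval outside transcript blocks for ", transcript_id)
  if (strand == "-") c(b, a + 1L) else c(a, b + 1L)
}

#' Validate a transcript-model table
#'
#' Enforces the coordinate invariants (0 <= cds_start < cds_end <= length,
#' unique transcript ids) and sets `cds_frame_ok` to flag CDS intervals whose
#' length is not a multiple of 3. If sequences are attached their lengths are
#' checked against `length`.
#'
#' @param models a `data.table` with columns `transcript_id`, `gene_id`,
#'   `length`, `cds_start`, `cds_end` and optionally `sequence`.
#' @return the validated table (invisibly modified by reference is avoided;
#'   a copy is returned).
#' @export
validate_transcript_models <- function(models) {
  models <- as.data.table(models)
  req <- c("transcript_id", "gene_id", "length", "cds_start", "cds_end")
  miss <- setdiff(req, names(models))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  dup <- models$transcript_id[duplicated(models$transcript_id)]
  if (length(dup)) stop("duplicate transcript ids: ", paste(unique(dup), collapse = ", "))
  bad <- models[!(cds_start >= 0L & cds_start < cds_end & cds_end <= length)]
  if (nrow(bad))
    stop("CDS outside transcript bounds for: ",
         paste(head(bad$transcript_id, 5L), collapse = ", "))
  models[, cds_frame_ok := ((cds_end - cds_start) %% 3L) == 0L]
  if (any(!models$cds_frame_ok))
    warning(sum(!models$cds_frame_ok),
            " transcript(s) flagged: CDS length not a multiple of 3")
  if (!"sequence" %in% names(models)) models[, sequence := NA_character_]
  has_seq <- !is.na(models$sequence)
  if (any(has_seq)) {
    bad_len <- models[has_seq][nchar(sequence) != length]
    if (nrow(bad_len))
      stop("sequence length != transcript length for: ",
           paste(head(bad_len$transcript_id, 5L), collapse = ", "))
  }
  setcolorder(models, c(req, "cds_frame_ok", "sequence"))
  models[]
}

#' Attach transcript sequences from FASTA
#'
#' FASTA ids (first whitespace-delimited token) must match `transcript_id`.
#' Sequences are stored uppercase with U converted to T.
#'
#' @param models transcript-model table from [read_annotation()].
#' @param fasta path to a FASTA file, or a named character vector /
#'   `Biostrings::DNAStringSet`.
#' @export
attach_sequences <- function(models, fasta) {
  seqs <- if (is.character(fasta) && length(fasta) == 1L && file.exists(fasta)) {
    x <- Biostrings::readDNAStringSet(fasta)
    setNames(as.character(x), sub("\\s.*$", "", names(x)))
  } else if (inherits(fasta, "XStringSet")) {
    setNames(as.character(fasta), sub("\\s.*$", "", names(fasta)))
  } else if (is.character(fasta)) {
    fasta
  } else stop("fasta must be a file path, named character vector or DNAStringSet")
  seqs <- chartr("u", "t", seqs)
  seqs <- toupper(seqs)
  seqs <- chartr("U", "T", seqs)
  models <- as.data.table(models)
  missing_ids <- setdiff(models$transcript_id, names(seqs))
  if (length(missing_ids))
    stop("no sequence for: ", paste(head(missing_ids, 5L), collapse = ", "))
  models[, sequence := unname(seqs[transcript_id])]
  validate_transcript_models(models)
}

#' Region of transcript positions
#'
#' Maps 0-based transcript offsets to `"utr5"`, `"cds"` or `"utr3"` by
#' half-open interval membership: `[0, cds_start)` is 5'UTR,
#' `[cds_start, cds_end)` is CDS, `[cds_end, length)` is 3'UTR.
#'
#' @param models transcript-model table.
#' @param transcript_id character vector (recycled against `pos`).
#' @param pos integer vector of 0-based offsets.
#' @return character vector of region labels.
#' @export
region_of <- function(models, transcript_id, pos) {
  n <- max(length(transcript_id), length(pos))
  transcript_id <- rep_len(transcript_id, n)
  pos <- rep_len(as.integer(pos), n)
  m <- match(transcript_id, models$transcript_id)
  if (anyNA(m)) stop("unknown transcript id(s): ",
                     paste(head(unique(transcript_id[is.na(m)]), 5L), collapse = ", "))
  len <- models$length[m]; cs <- models$cds_start[m]; ce <- models$cds_end[m]
  if (any(pos < 0L | pos >= len)) stop("position out of transcript bounds")
  ifelse(pos < cs, "utr5", ifelse(pos < ce, "cds", "utr3"))
}

#' Write transcript models as transcript-space BED12
#'
#' Each transcript becomes a single-block BED12 record on its own "chromosome"
#' (the transcript itself), with the CDS as the thick interval and the name
#' `"<transcript_id>|<gene_id>"`, so that [read_annotation()] round-trips the
#' model set.
#'
#' @param models transcript-model table.
#' @param path output file.
#' @export
write_annotation <- function(models, path) {
  models <- as.data.table(models)
  bed <- models[, .(
    chrom = transcript_id, chromStart = 0L, chromEnd = length,
    name = paste0(transcript_id, "|", gene_id), score = 0L, strand = "+",
    thickStart = cds_start, thickEnd = cds_end, itemRgb = "0",
    blockCount = 1L, blockSizes = paste0(length, ","), blockStarts = "0,"
  )]
  fwrite(bed, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pick one canonical transcript per gene
#'
#' Gene-level quantities use a designated transcript per gene. The default
#' rule keeps the transcript with the longest CDS (ties broken by transcript
#' id, alphabetically, for determinism).
#'
#' @param models transcript-model table.
#' @param by `"longest_cds"` or `"longest_transcript"`.
#' @return a `data.table` mapping `gene_id` to the chosen `transcript_id`.
#' @export
canonical_transcripts <- function(models, by = c("longest_cds", "longest_transcript")) {
  by <- match.arg(by)
  models <- as.data.table(models)
  key <- if (by == "longest_cds") models$cds_end - models$cds_start else models$length
  dt <- data.table(gene_id = models$gene_id, transcript_id = models$transcript_id, k = key)
  setorder(dt, gene_id, -k, transcript_id)
  dt[, .(transcript_id = transcript_id[1L]), by = gene_id]
}
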