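#' P-site offset configuration
#'
#' The ribosomal P-site is inferred from a read's 5' end plus a fixed offset.
#' The default 12 nt is the standard choice for ~30-nt mammalian ribosome
#' footprints; offsets can be overridden per read length
#' (e.g. `psite_offsets(by_length = c("31" = 13))`). RNA-seq reads are
#' positional only through their 5' end, so the `rna` offset is 0.
#'
#' @param default offset (nt) applied to read lengths without a specific entry.
#' @param by_length named integer vector, names are read lengths.
#' @export
psite_offsets <- function(default = 12L, by_length = integer()) {
  stopifnot(length(default) == 1L, default >= 0L)
  if (length(by_length) && is.null(names(by_length)))
    stop("by_length must be named by read length")
  structure(list(default = as.integer(default),
                 by_length = vapply(by_length, as.integer, integer(1))),
            class = "psite_offsets")
}

#' P-site position of reads
#'
#' `psite = start + offset[read_length]` (the default offset where no
#' per-length entry exists). Positions are not range-checked here; see
#' [assign_psites()] which flags and excludes P-sites falling beyond the
#' transcript end.
#'
#' @param start 0-based read starts.
#' @param read_length read lengths (nt).
#' @param offsets a [psite_offsets()] object.
#' @return integer vector of 0-based P-site offsets.
#' @export
psite <- function(start, read_length, offsets = psite_offsets()) {
  stopifnot(inherits(offsets, "psite_offsets"))
  off <- rep(offsets$default, length(start))
  if (length(offsets$by_length)) {
    m <- match(as.character(read_length), names(offsets$by_length))
    off[!is.na(m)] <- offsets$by_length[m[!is.na(m)]]
  }
  as.integer(start) + off
}

#' Filter reads by minimum length
#'
#' Reads shorter than `min_len` nucleotides are excluded; input order is
#' preserved.
#'
#' @param aln alignment table.
#' @param min_len minimum retained read length (default 20 nt).
#' @export
filter_reads <- function(aln, min_len = 20L) {
  as.data.table(aln)[read_length >= min_len]
}

#' Assign P-sites and regions to reads
#'
#' Adds `psite` and `region` columns. RPF reads use the configured offsets;
#' RNA reads use offset 0 (their 5' end). Reads whose P-site falls outside
#' the transcript, or that align to an unknown transcript, are excluded with
#' a message (they carry no usable positional information).
#'
#' @param aln alignment table.
#' @param models transcript-model table.
#' @param offsets a [psite_offsets()] for the RPF library.
#' @export
assign_psites <- function(aln, models, offsets = psite_offsets()) {
  aln <- copy(as.data.table(aln))
  models <- as.data.table(models)
  m <- match(aln$transcript_id, models$transcript_id)
  unknown <- is.na(m)
  if (any(unknown)) {
    message(sum(unknown), " read(s) on unknown transcripts excluded")
    aln <- aln[!unknown]; m <- m[!unknown]
  }
  ps <- ifelse(aln$library == "rpf",
               psite(aln$start, aln$read_length, offsets),
               aln$start)
  len <- models$length[m]
  ok <- ps >= 0L & ps < len
  if (any(!ok)) message(sum(!ok), " read(s) with P-site outside transcript excluded")
  aln[, psite := as.integer(ps)]
  aln <- aln[ok]
  m <- m[ok]
  cs <- models$cds_start[m]; ce <- models$cds_end[m]
  aln[, region := ifelse(psite < cs, "utr5", ifelse(psite < ce, "cds", "utr3"))]
  aln[]
}

#' Per-transcript region counts
#'
#' Counts reads per transcript x sample x library falling in 5'UTR, CDS and
#' 3'UTR (by P-site for RPF, by 5' end for RNA).
#'
#' @param aln alignment table (will be passed through [assign_psites()] if it
#'   lacks a `region` column).
#' @inheritParams assign_psites
#' @return `data.table` with `transcript_id`, `sample_id`, `library`,
#'   `n_utr5`, `n_cds`, `n_utr3`, `n_total`.
#' @export
region_counts <- function(aln, models, offsets = psite_offsets()) {
  aln <- as.data.table(aln)
  if (!"region" %in% names(aln)) aln <- assign_psites(aln, models, offsets)
  rc <- dcast(aln[, .N, by = .(transcript_id, sample_id, library, region)],
              transcript_id + sample_id + library ~ region,
              value.var = "N", fill = 0L)
  for (col in c("utr5", "cds", "utr3"))
    if (!col %in% names(rc)) rc[, (col) := 0L]
  setnames(rc, c("utr5", "cds", "utr3"), c("n_utr5", "n_cds", "n_utr3"))
  rc[, n_total := n_utr5 + n_cds + n_utr3]
  setcolorder(rc, c("transcript_id", "sample_id", "library",
                    "n_utr5", "n_cds", "n_utr3", "n_total"))
  rc[]
}

#' Region occupancy distribution of RPF reads
#'
#' Percentage of RPF P-sites in 5'UTR, CDS and 3'UTR across all reads with a
#' valid P-site. With zero usable reads the result is an explicit empty
#' (zero-row) table, never NaN percentages.
#'
#' @inheritParams region_counts
#' @return `data.table` with `region`, `n`, `pct` (percentages sum to 100).
#' @export
region_distribution <- function(aln, models, offsets = psite_offsets()) {
  aln <- as.data.table(aln)
  if (!"region" %in% names(aln)) aln <- assign_psites(aln, models, offsets)
  aln <- aln[library == "rpf"]
  if (nrow(aln) == 0L) {
    message("no usable RPF reads; empty region distribution")
    return(data.table(region = character(), n = integer(), pct = numeric()))
  }
  out <- aln[, .(n = .N), by = region]
  out <- out[data.table(region = c("utr5", "cds", "utr3")), on = "region"]
  out[is.na(n), n := 0L]
  out[, pct := 100 * n / sum(n)]
  out[]
}

#' Reading-frame distribution of CDS P-sites
#'
#' Only RPF reads whose P-site falls in the CDS contribute. The frame is
#' `(psite - cds_start) mod 3`; frame 0 is the annotated reading frame
#' ("in-frame"). With no CDS P-sites the result is an explicit empty table.
#'
#' @inheritParams region_counts
#' @return `data.table` with `frame` (0,1,2), `n`, `pct`.
#' @export
frame_distribution <- function(aln, models, offsets = psite_offsets()) {
  aln <- as.data.table(aln)
  if (!"region" %in% names(aln)) aln <- assign_psites(aln, models, offsets)
  aln <- aln[library == "rpf" & region == "cds"]
  if (nrow(aln) == 0L) {
    message("no CDS P-sites; empty frame distribution")
    return(data.table(frame = integer(), n = integer(), pct = numeric()))
  }
  models <- as.data.table(models)
  cs <- models$cds_start[match(aln$transcript_id, models$transcript_id)]
  fr <- (aln$psite - cs) %% 3L
  out <- data.table(frame = fr)[, .(n = .N), by = frame]
  out <- out[data.table(frame = 0:2), on = "frame"]
  out[is.na(n), n := 0L]
  setorder(out, frame)
  out[, pct := 100 * n / sum(n)]
  out[]
}

#' Read-length histogram
#'
#' Exact multiset histogram of read lengths.
#' @param aln alignment table.
#' @return `data.table` with `read_length`, `n`, sorted by length; zero rows
#'   for empty input.
#' @export
length_histogram <- function(aln) {
  aln <- as.data.table(aln)
  if (nrow(aln) == 0L) return(data.table(read_length = integer(), n = integer()))
  out <- aln[, .(n = .N), by = read_length]
  setorder(out, read_length)
  out[]
}

#' Reads per kilobase per million mapped reads
#'
#' `count / (feature_len/1000) / (lib_size/1e6)`. For RPF libraries the count
#' is CDS-assigned reads over the CDS length; for RNA libraries it is all
#' reads on the transcript over the transcript length. RPKM and FPKM coincide
#' for single-end libraries and are used interchangeably here.
#'
#' @param count read counts (vectorised).
#' @param feature_len feature length in nt (> 0).
#' @param lib_size total mapped reads in the library (> 0).
#' @export
rpkm <- function(count, feature_len, lib_size) {
  if (any(feature_len <= 0)) stop("feature_len must be > 0")
  if (any(lib_size <= 0)) stop("lib_size must be > 0")
  count / (feature_len / 1e3) / (lib_size / 1e6)
}

#' Translation efficiency
#'
#' TE is the ratio of ribosome footprint density to mRNA abundance:
#' CDS-restricted Ribo-seq RPKM over whole-transcript RNA-seq FPKM. Below the
#' expression floor the ratio is numerically unstable and TE is undefined
#' (`NA`), which downstream steps treat as "excluded", not as an error.
#'
#' @param ribo_rpkm CDS-restricted Ribo-seq RPKM.
#' @param rna_fpkm whole-transcript RNA-seq FPKM.
#' @param floor minimum `rna_fpkm` for TE to be defined (default 1).
#' @export
translation_efficiency <- function(ribo_rpkm, rna_fpkm, floor = 1) {
  if (any(ribo_rpkm < 0, na.rm = TRUE) || any(rna_fpkm < 0, na.rm = TRUE))
    stop("RPKM values must be >= 0")
  ifelse(!is.na(rna_fpkm) & rna_fpkm >= floor, ribo_rpkm / rna_fpkm, NA_real_)
}

#' Effective library sizes for RPKM
#'
#' `"total"` returns raw per-sample read totals. `"median_ratio"` computes
#' median-of-ratios size factors per sample within each library type (RNA on
#' whole-transcript counts, RPF on CDS counts; reference = per-transcript
#' geometric mean over samples, restricted to transcripts counted in every
#' sample) and rescales them so their geometric mean equals the geometric
#' mean of the raw totals, keeping FPKM magnitudes comparable to the
#' unnormalised ones. Falls back to totals with a message when fewer than 10
#' transcripts are usable for the reference.
#'
#' @param rc region-count table ([region_counts()]).
#' @param normalize `"median_ratio"` or `"total"`.
#' @return `data.table`: `sample_id`, `library`, `lib_size`.
#' @export
effective_library_sizes <- function(rc, normalize = c("median_ratio", "total")) {
  normalize <- match.arg(normalize)
  rc <- as.data.table(rc)
  totals <- rc[, .(total = sum(n_total)), by = .(sample_id, library)]
  if (normalize == "total")
    return(totals[, .(sample_id, library, lib_size = as.numeric(total))])
  out <- vector("list", 0L)
  for (lib in unique(rc$library)) {
    sub <- rc[library == lib]
    sub[, count := if (lib == "rpf") n_cds else n_total]
    w <- dcast(sub, transcript_id ~ sample_id, value.var = "count", fill = 0L)
    mat <- as.matrix(w[, -1L])
    tot <- totals[library == lib][match(colnames(mat), sample_id), total]
    pos <- rowSums(mat > 0L) == ncol(mat)
    sf <- if (sum(pos) < 10L) {
      message("too few transcripts for median-ratio size factors (",
              lib, "); using raw totals")
      tot / exp(mean(log(tot)))
    } else {
      ref <- exp(rowMeans(log(mat[pos, , drop = FALSE])))
      apply(mat[pos, , drop = FALSE], 2L, function(cnt) median(cnt / ref))
    }
    sf <- sf / exp(mean(log(sf)))
    out[[lib]] <- data.table(sample_id = colnames(mat), library = lib,
                             lib_size = sf * exp(mean(log(tot))))
  }
  rbindlist(out)
}

#' Library sizes
#'
#' Total reads per sample x library after length filtering and transcript
#' assignment: the denominator of [rpkm()].
#'
#' @param aln alignment table (post-filter).
#' @export
library_sizes <- function(aln) {
  as.data.table(aln)[, .(lib_size = .N), by = .(sample_id, library)]
}

#' Per-gene quantification
#'
#' Builds the gene x sample quantification table: whole-transcript RNA FPKM,
#' CDS-restricted Ribo-seq RPKM, and TE. Genes are represented by a canonical
#' transcript ([canonical_transcripts()], longest CDS by default). Every
#' gene x sample cell is reported (zero counts included) for each library
#' present in the data.
#'
#' @param rc region-count table from [region_counts()].
#' @param models transcript-model table.
#' @param canonical optional `gene_id`/`transcript_id` map; computed from
#'   `models` when `NULL`.
#' @param te_floor expression floor passed to [translation_efficiency()].
#' @param lib_sizes optional precomputed [library_sizes()]-style table,
#'   overriding `normalize`.
#' @param normalize how the RPKM denominator (library size) is obtained.
#'   `"median_ratio"` (default) computes DESeq-style median-of-ratios size
#'   factors per sample within each library type and scales them to the
#'   geometric mean of the raw per-sample totals, making fold changes robust
#'   to composition shifts (a handful of strongly induced genes consuming a
#'   large share of one library's reads); `"total"` uses the raw per-sample
#'   read totals.
#' @return `data.table` with `gene_id`, `transcript_id`, `sample_id`,
#'   `rna_count`, `ribo_cds_count`, `rna_fpkm`, `ribo_rpkm`, `te`.
#' @export
gene_quant <- function(rc, models, canonical = NULL, te_floor = 1,
                       lib_sizes = NULL,
                       normalize = c("median_ratio", "total")) {
  normalize <- match.arg(normalize)
  rc <- as.data.table(rc)
  models <- as.data.table(models)
  if (is.null(canonical)) canonical <- canonical_transcripts(models)
  if (is.null(lib_sizes))
    lib_sizes <- effective_library_sizes(rc, normalize)
  samples <- unique(rc$sample_id)
  ct <- canonical[models, on = "transcript_id", nomatch = 0L][
    , .(gene_id, transcript_id, length, cds_len = cds_end - cds_start)]
  grid <- CJ(transcript_id = ct$transcript_id, sample_id = samples,
             unique = TRUE)
  grid <- ct[grid, on = "transcript_id"]

  rna <- rc[library == "rna", .(transcript_id, sample_id, rna_count = n_total)]
  ribo <- rc[library == "rpf", .(transcript_id, sample_id, ribo_cds_count = n_cds)]
  gq <- rna[grid, on = c("transcript_id", "sample_id")]
  gq <- ribo[gq, on = c("transcript_id", "sample_id")]
  gq[is.na(rna_count), rna_count := 0L]
  gq[is.na(ribo_cds_count), ribo_cds_count := 0L]

  ls_rna <- lib_sizes[library == "rna", .(sample_id, rna_lib = lib_size)]
  ls_rpf <- lib_sizes[library == "rpf", .(sample_id, rpf_lib = lib_size)]
  gq <- ls_rna[gq, on = "sample_id"]
  gq <- ls_rpf[gq, on = "sample_id"]
  gq[, `:=`(rna_fpkm = NA_real_, ribo_rpkm = NA_real_)]
  gq[!is.na(rna_lib), rna_fpkm := rpkm(rna_count, length, rna_lib)]
  gq[!is.na(rpf_lib), ribo_rpkm := rpkm(ribo_cds_count, cds_len, rpf_lib)]
  gq[, te := translation_efficiency(ribo_rpkm, rna_fpkm, floor = te_floor)]
  out <- gq[, .(gene_id, transcript_id, sample_id, rna_count, ribo_cds_count,
                rna_fpkm, ribo_rpkm, te)]
  setorder(out, gene_id, sample_id)
  out[]
}
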