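test_that("single-exon BED12 maps identically into transcript space", {
  bed <- c(
    "chr1\t0\t1000\ttx1|g1\t0\t+\t100\t700\t0\t1\t1000,\t0,",
    "chr1\t0\t500\ttx2|g1\t0\t+\t0\t300\t0\t1\t500,\t0,"   # no 5'UTR
  )
  f <- withr::local_tempfile(lines = bed, fileext = ".bed")
  m <- read_annotation(f, format = "bed12")
  expect_equal(nrow(m), 2L)
  t1 <- m[m$transcript_id == "tx1"]
  expect_equal(t1$length, 1000L)
  expect_equal(t1$cds_start, 100L)
  expect_equal(t1$cds_end, 700L)
  expect_equal(t1$gene_id, "g1")
  t2 <- m[m$transcript_id == "tx2"]
  expect_equal(t2$cds_start, 0L)          # thickStart == chromStart
  expect_equal(t2$cds_end, 300L)
})

test_that("multi-exon CDS coordinates match a brute-force per-base map", {
  # 3 exons; CDS spans both junctions; checked on both strands against an
  # explicit genome->transcript base enumeration
  ex_start <- c(100L, 500L, 1200L)
  ex_end <- c(250L, 800L, 1500L)
  thick_s <- 180L; thick_e <- 1349L
  for (strand in c("+", "-")) {
    bed <- paste("chr2", 100, 1500, "txm|gm", 0, strand, thick_s, thick_e, 0,
                 3, paste0(paste(ex_end - ex_start, collapse = ","), ","),
                 paste0(paste(ex_start - 100L, collapse = ","), ","),
                 sep = "\t")
    f <- withr::local_tempfile(lines = bed, fileext = ".bed")
    m <- read_annotation(f, format = "bed12")
    # oracle: list genomic bases of the transcript in transcript order
    gbases <- unlist(mapply(function(s, e) s:(e - 1L), ex_start, ex_end))
    if (strand == "-") gbases <- rev(gbases)
    cds_bases <- which(gbases >= thick_s & gbases < thick_e)  # 1-based tx pos
    expect_equal(m$length, length(gbases))
    expect_equal(m$cds_start, min(cds_bases) - 1L)
    expect_equal(m$cds_end, max(cds_bases))
  }
})

test_that("GTF input yields the same model as the equivalent BED12", {
  ex_start <- c(100L, 500L, 1200L); ex_end <- c(250L, 800L, 1500L)
  thick_s <- 180L; thick_e <- 1349L
  bed <- paste("chr2", 100, 1500, "txm|gm", 0, "+", thick_s, thick_e, 0, 3,
               paste0(paste(ex_end - ex_start, collapse = ","), ","),
               paste0(paste(ex_start - 100L, collapse = ","), ","), sep = "\t")
  fb <- withr::local_tempfile(lines = bed, fileext = ".bed")
  attrs <- 'gene_id "gm"; transcript_id "txm";'
  gtf <- c(
    sprintf("chr2\tt\texon\t%d\t%d\t.\t+\t.\t%s", ex_start + 1L, ex_end, attrs),
    # CDS features clipped to exon intersections
    sprintf("chr2\tt\tCDS\t%d\t%d\t.\t+\t0\t%s", 181L, 250L, attrs),
    sprintf("chr2\tt\tCDS\t%d\t%d\t.\t+\t0\t%s", 501L, 800L, attrs),
    sprintf("chr2\tt\tCDS\t%d\t%d\t.\t+\t0\t%s", 1201L, 1349L, attrs))
  fg <- withr::local_tempfile(lines = gtf, fileext = ".gtf")
  mb <- read_annotation(fb, format = "bed12")
  mg <- read_annotation(fg, format = "gtf")
  expect_equal(mg$length, mb$length)
  expect_equal(mg$cds_start, mb$cds_start)
  expect_equal(mg$cds_end, mb$cds_end)
  expect_equal(mg$gene_id, "gm")
})

test_that("region_of follows the half-open convention and matches a per-base oracle", {
  models <- random_models(25, seed = 101)
  # boundary conventions on one transcript with non-empty UTRs
  tx <- models[models$cds_start > 0 & models$cds_end < models$length][1L]
  expect_equal(region_of(models, tx$transcript_id, tx$cds_start), "cds")
  expect_equal(region_of(models, tx$transcript_id, tx$cds_start - 1L), "utr5")
  expect_equal(region_of(models, tx$transcript_id, tx$cds_end - 1L), "cds")
  expect_equal(region_of(models, tx$transcript_id, tx$cds_end), "utr3")
  expect_error(region_of(models, tx$transcript_id, tx$length), "bounds")
  expect_error(region_of(models, tx$transcript_id, -1L), "bounds")

  # 10,000 random (tx, pos) pairs against the per-base lookup table
  tables <- lapply(seq_len(nrow(models)), function(i)
    oracle_region_table(models$length[i], models$cds_start[i], models$cds_end[i]))
  withr::with_seed(202, {
    i <- sample(nrow(models), 10000, replace = TRUE)
    pos <- floor(runif(10000) * models$length[i])
  })
  got <- region_of(models, models$transcript_id[i], pos)
  want <- vapply(seq_along(i), function(j) tables[[i[j]]][pos[j] + 1L], "")
  expect_identical(got, want)
})

test_that("per-base region labels partition every transcript exactly", {
  models <- random_models(40, seed = 303)
  for (i in seq_len(nrow(models))) {
    lab <- region_of(models, models$transcript_id[i],
                     seq_len(models$length[i]) - 1L)
    cnt <- table(factor(lab, levels = c("utr5", "cds", "utr3")))
    expect_equal(unname(cnt[["utr5"]]), models$cds_start[i])
    expect_equal(unname(cnt[["cds"]]), models$cds_end[i] - models$cds_start[i])
    expect_equal(unname(cnt[["utr3"]]), models$length[i] - models$cds_end[i])
  }
})

test_that("annotation round-trips through write_annotation", {
  models <- random_models(15, seed = 404)
  f <- withr::local_tempfile(fileext = ".bed")
  write_annotation(models, f)
  back <- read_annotation(f, format = "bed12")
  cols <- c("transcript_id", "gene_id", "length", "cds_start", "cds_end")
  expect_equal(as.data.frame(back[order(transcript_id), ..cols]),
               as.data.frame(models[order(transcript_id), ..cols]))
})

test_that("invalid annotation is rejected and frame anomalies are flagged", {
  good <- data.table::data.table(
    transcript_id = "t1", gene_id = "g1", length = 100L,
    cds_start = 10L, cds_end = 70L)
  expect_silent(validate_transcript_models(good))
  dup <- rbind(good, good)
  expect_error(validate_transcript_models(dup), "duplicate")
  oob <- data.table::copy(good)[, cds_end := 200L]
  expect_error(validate_transcript_models(oob), "bounds")
  offframe <- data.table::copy(good)[, cds_end := 71L]
  expect_warning(v <- validate_transcript_models(offframe), "multiple of 3")
  expect_false(v$cds_frame_ok)
  # attached sequence must match the declared length
  withseq <- data.table::copy(good)
  expect_error(attach_sequences(withseq, c(t1 = "ACGT")), "length")
})
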