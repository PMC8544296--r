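make_aln <- function(tx, start, len, sample = "s1", lib = "rpf") {
  data.table::data.table(transcript_id = tx, start = as.integer(start),
                         read_length = as.integer(len), sample_id = sample,
                         library = lib)
}

test_that("filter_reads keeps exactly the reads at or above the length floor", {
  aln <- make_aln("t1", c(0, 5, 9), c(19, 20, 21))
  expect_equal(filter_reads(aln)$read_length, c(20L, 21L))
  expect_equal(nrow(filter_reads(aln[0])), 0L)
  # random multiset vs brute-force subset, order preserved
  withr::with_seed(11, lens <- sample(15:35, 1000, replace = TRUE))
  aln2 <- make_aln("t1", seq_along(lens), lens)
  got <- filter_reads(aln2, min_len = 24L)
  expect_identical(got$read_length, lens[lens >= 24L])
  expect_identical(got$start, aln2$start[lens >= 24L])
})

test_that("psite is start plus the per-length offset", {
  expect_equal(psite(100L, 30L), 112L)
  offs <- psite_offsets(default = 12L, by_length = c("30" = 12, "29" = 12, "31" = 13))
  expect_equal(psite(0L, 31L, offs), 13L)
  expect_equal(psite(c(10L, 20L), c(30L, 31L), offs), c(22L, 33L))
})

test_that("P-site regions match the per-base oracle and bad P-sites are dropped", {
  models <- random_models(10, seed = 55)
  tables <- lapply(seq_len(nrow(models)), function(i)
    oracle_region_table(models$length[i], models$cds_start[i], models$cds_end[i]))
  withr::with_seed(56, {
    i <- sample(nrow(models), 2000, replace = TRUE)
    st <- floor(runif(2000) * (models$length[i] - 30))
  })
  aln <- make_aln(models$transcript_id[i], st, 30L)
  got <- assign_psites(aln, models)
  want <- vapply(seq_len(nrow(got)), function(j) {
    k <- match(got$transcript_id[j], models$transcript_id)
    tables[[k]][got$psite[j] + 1L]
  }, "")
  expect_identical(got$region, want)
  # a read whose P-site lands beyond the transcript end is excluded
  short <- validate_transcript_models(data.table::data.table(
    transcript_id = "s", gene_id = "s", length = 40L, cds_start = 0L, cds_end = 39L))
  suppressWarnings(expect_message(
    out <- assign_psites(make_aln("s", 35L, 30L), short), "outside"))
  expect_equal(nrow(out), 0L)
})

test_that("region_distribution handles pure and degenerate compositions", {
  models <- validate_transcript_models(data.table::data.table(
    transcript_id = "t", gene_id = "g", length = 300L,
    cds_start = 90L, cds_end = 240L))
  all_cds <- make_aln("t", seq(80, 200, by = 10), 30L)  # psites 92..212
  d <- region_distribution(all_cds, models)
  expect_equal(d[d$region == "cds", pct], 100)
  expect_equal(sum(d$pct), 100, tolerance = 1e-9)
  two <- make_aln("t", c(0L, 240L), 30L)                # psites 12 and 252
  d2 <- region_distribution(two, models)
  expect_equal(d2[d2$region == "utr5", pct], 50)
  expect_equal(d2[d2$region == "utr3", pct], 50)
  expect_equal(d2[d2$region == "cds", pct], 0)
  expect_message(d0 <- region_distribution(all_cds[0], models), "empty")
  expect_equal(nrow(d0), 0L)
})

test_that("frame_distribution uses (psite - cds_start) mod 3 on CDS reads only", {
  models <- validate_transcript_models(data.table::data.table(
    transcript_id = "t", gene_id = "g", length = 300L,
    cds_start = 90L, cds_end = 240L))
  # P-sites at cds_start + 3k -> all frame 0
  aln <- make_aln("t", 90L + 3L * (0:20) - 12L, 30L)
  f <- frame_distribution(aln, models)
  expect_equal(f$pct, c(100, 0, 0))
  # single read at cds_start + 4 -> frame 1
  f1 <- frame_distribution(make_aln("t", 90L + 4L - 12L, 30L), models)
  expect_equal(f1$pct, c(0, 100, 0))
  # invariance: shifting every P-site by +3 within the CDS keeps frames
  aln2 <- make_aln("t", 90L + c(0, 1, 2, 4, 8) - 12L, 30L)
  aln3 <- data.table::copy(aln2)[, start := start + 3L]
  expect_equal(frame_distribution(aln2, models)$pct,
               frame_distribution(aln3, models)$pct)
  expect_message(f0 <- frame_distribution(make_aln("t", 0L, 30L), models),
                 "no CDS")
  expect_equal(nrow(f0), 0L)
})

test_that("length_histogram is an exact multiset histogram", {
  h <- length_histogram(make_aln("t", c(0, 1, 2), c(30, 30, 28)))
  expect_equal(h$read_length, c(28L, 30L))
  expect_equal(h$n, c(1L, 2L))
  expect_equal(nrow(length_histogram(make_aln("t", 1, 30)[0])), 0L)
  st <- small_study()
  h2 <- length_histogram(st$alignments[library == "rpf"])
  expect_equal(h2$read_length[which.max(h2$n)], 30L)   # configured modal length
})

test_that("rpkm matches its closed form, is linear in count, inverse in depth", {
  expect_equal(rpkm(10, 1000, 1e6), 10)
  expect_equal(rpkm(0, 500, 2e6), 0)
  withr::with_seed(77, {
    cnt <- sample(0:5000, 200, replace = TRUE)
    len <- sample(100:5000, 200, replace = TRUE)
    lib <- sample(1e5:1e7, 200, replace = TRUE)
  })
  expect_equal(rpkm(cnt, len, lib), cnt * 1e9 / (as.numeric(len) * lib),
               tolerance = 1e-12)
  expect_equal(rpkm(2 * cnt, len, lib), 2 * rpkm(cnt, len, lib))
  expect_equal(rpkm(cnt, len, 2 * lib), rpkm(cnt, len, lib) / 2)
  expect_error(rpkm(1, 0, 1e6), "feature_len")
  expect_error(rpkm(1, 100, 0), "lib_size")
})

test_that("translation efficiency is the density ratio with an expression floor", {
  expect_equal(translation_efficiency(20, 10), 2)
  expect_true(is.na(translation_efficiency(5, 0)))
  expect_true(is.na(translation_efficiency(5, 0.5, floor = 1)))
  expect_equal(translation_efficiency(5, 0.5, floor = 0.1), 10)
  expect_error(translation_efficiency(-1, 2), ">= 0")
})

test_that("region and frame mixtures are recovered from a homogeneous simulation", {
  st <- uniform_occ_study()   # occupancies (0.07, 0.90, 0.03), frames (.75,.15,.10)
  aln <- assign_psites(filter_reads(st$alignments), st$models)
  d <- region_distribution(aln, st$models)
  expect_lt(abs(d[d$region == "utr5", pct] - 7), 0.5)
  expect_lt(abs(d[d$region == "cds", pct] - 90), 0.5)
  expect_lt(abs(d[d$region == "utr3", pct] - 3), 0.5)
  f <- frame_distribution(aln, st$models)
  expect_true(all(abs(f$pct - c(75, 15, 10)) < 0.5))
})

test_that("median-ratio library sizes equal raw totals under equal composition", {
  q <- small_quant()
  tot <- library_sizes(q$aln)
  eff <- effective_library_sizes(q$rc, normalize = "total")
  m <- merge(tot, eff, by = c("sample_id", "library"))
  expect_equal(m$lib_size.x, m$lib_size.y)
  # with no differential effects the composition is constant across samples,
  # so median-ratio sizes reduce to the raw totals up to counting noise
  null_st <- fixture("null_small_study", function() simulate_study(
    sim_config(n_genes = 60, reads_per_library = 3e4, seed = 47)))
  null_aln <- assign_psites(filter_reads(null_st$alignments), null_st$models)
  null_rc <- region_counts(null_aln, null_st$models)
  mr <- merge(effective_library_sizes(null_rc, normalize = "median_ratio"),
              effective_library_sizes(null_rc, normalize = "total"),
              by = c("sample_id", "library"))
  expect_true(all(abs(log(mr$lib_size.x / mr$lib_size.y)) < 0.15))
})
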