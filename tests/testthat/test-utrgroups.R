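rc_row <- function(tx, u5, cds, u3, sample = "s1", lib = "rpf") {
  data.table::data.table(transcript_id = tx, sample_id = sample, library = lib,
                         n_utr5 = as.integer(u5), n_cds = as.integer(cds),
                         n_utr3 = as.integer(u3),
                         n_total = as.integer(u5 + cds + u3))
}

test_that("utr5_index is the 5'UTR read fraction with the >0 selection rule", {
  rc <- rbind(rc_row("t1", 5, 15, 0),
              rc_row("t2", 0, 40, 2),     # excluded: no 5'UTR reads
              rc_row("t3", 8, 0, 0),      # all reads in the 5'UTR
              rc_row("t4", 0, 0, 0))      # skipped: no reads at all
  expect_message(idx <- utr5_index(rc), "zero reads")
  expect_setequal(idx$transcript_id, c("t1", "t3"))
  expect_equal(idx[idx$transcript_id == "t1", utr5_index], 0.25)
  expect_equal(idx[idx$transcript_id == "t3", utr5_index], 1)
  # invariance to scaling all counts by a common factor
  rc10 <- data.table::copy(rc)[, c("n_utr5", "n_cds", "n_utr3", "n_total") :=
                                 lapply(.SD, function(x) x * 10L),
                               .SDcols = c("n_utr5", "n_cds", "n_utr3", "n_total")]
  suppressMessages(idx10 <- utr5_index(rc10))
  expect_equal(idx10$utr5_index, idx$utr5_index)
})

test_that("replicates pool within condition when a sample sheet is given", {
  rc <- rbind(rc_row("t1", 2, 18, 0, sample = "c1"),
              rc_row("t1", 4, 16, 0, sample = "c2"))
  sheet <- data.table::data.table(sample_id = c("c1", "c2"),
                                  condition = "ctrl")
  idx <- utr5_index(rc, samples = sheet)
  expect_equal(nrow(idx), 1L)
  expect_equal(idx$utr5_index, 6 / 40)
})

test_that("split_high_low is a deterministic median split", {
  rec <- data.table::data.table(
    transcript_id = paste0("t", 1:4), condition = "ctrl",
    utr5_reads = 1L, total_reads = 10L, utr5_index = c(0.1, 0.2, 0.3, 0.4))
  hl <- split_high_low(rec)
  expect_setequal(hl[hl$group == "low_UTR", utr5_index], c(0.1, 0.2))
  expect_setequal(hl[hl$group == "high_UTR", utr5_index], c(0.3, 0.4))
  # odd n: the median record goes to low_UTR
  rec5 <- data.table::data.table(
    transcript_id = paste0("t", 1:5), utr5_index = c(0.5, 0.1, 0.3, 0.2, 0.4))
  hl5 <- split_high_low(rec5)
  expect_equal(sum(hl5$group == "low_UTR"), 3L)
  expect_true(hl5[hl5$utr5_index == 0.3, group] == "low_UTR")
  expect_error(split_high_low(data.table::data.table(
    transcript_id = c("a", "b"), utr5_index = c(0.2, 0.2))), "identical")
  # sort-based oracle over random vectors
  for (s in 1:20) {
    withr::with_seed(1000 + s, v <- runif(sample(3:40, 1)))
    rec_r <- data.table::data.table(
      transcript_id = sprintf("x%02d", seq_along(v)), utr5_index = v)
    hl_r <- split_high_low(rec_r)
    lo <- hl_r[hl_r$group == "low_UTR", utr5_index]
    hi <- hl_r[hl_r$group == "high_UTR", utr5_index]
    expect_lte(abs(length(lo) - length(hi)), 1L)
    expect_gte(min(hi), max(lo))
  }
})

test_that("compare_groups reproduces the classical tests closed-form", {
  # hand computation: groups {1,2,3},{2,3,4},{3,4,5}; grand mean 3
  # SSB = 3*((2-3)^2 + 0 + (4-3)^2) = 6 on 2 df; SSW = 2+2+2 = 6 on 6 df
  # F = (6/2)/(6/6) = 3
  v <- c(1, 2, 3, 2, 3, 4, 3, 4, 5)
  g <- rep(c("a", "b", "c"), each = 3)
  res <- compare_groups(v, g, test = "anova")
  expect_equal(unname(res$statistic), 3, tolerance = 1e-10)
  expect_equal(res$p_value, stats::pf(3, 2, 6, lower.tail = FALSE),
               tolerance = 1e-10)

  # classical pooled two-sample t computed from its textbook formula
  x <- c(2.1, 3.4, 2.8, 3.0); y <- c(4.0, 4.4, 3.7, 5.1)
  sp2 <- (3 * var(x) + 3 * var(y)) / 6
  t_hand <- (mean(y) - mean(x)) / sqrt(sp2 * (1 / 4 + 1 / 4))
  res_t <- compare_groups(c(x, y), rep(c("A", "B"), each = 4), test = "t_test")
  expect_equal(abs(unname(res_t$statistic)), abs(t_hand), tolerance = 1e-10)

  # degenerate: zero variance everywhere is flagged, not an exception
  resd <- compare_groups(rep(1, 6), rep(c("a", "b"), 3), test = "anova")
  expect_true(resd$degenerate)
  expect_true(is.na(resd$p_value))
  expect_error(compare_groups(1:3, c("a", "a", "b"), test = "t_test"),
               ">= 2 values")
  # Mann-Whitney route runs
  resw <- compare_groups(c(x, y), rep(c("A", "B"), each = 4),
                         test = "mannwhitney")
  expect_true(resw$p_value < 1)
})

test_that("uORF-shift genes lose 5'UTR density and gain TE; high_UTR gains most", {
  st <- fixture("shift_study_small", function() simulate_study(sim_config(
    n_genes = 300, reads_per_library = 6e4, uorf_fraction = 0.5,
    n_uorf_shift = 150, seed = 23)))
  aln <- assign_psites(filter_reads(st$alignments), st$models)
  rc <- region_counts(aln, st$models)
  gq <- gene_quant(rc, st$models)
  didx <- delta_utr5_index(rc, st$samples, "ctrl", "treat")
  dm <- merge(didx, st$truth[, c("transcript_id", "group")], by = "transcript_id")
  expect_lt(dm[dm$group == "uorf_shift", mean(delta_index)], -0.1)
  expect_lt(abs(dm[dm$group == "null", mean(delta_index)]), 0.05)

  suppressMessages(idx_ctrl <- utr5_index(
    rc[grepl("ctrl", sample_id)], samples = st$samples))
  hl <- split_high_low(idx_ctrl)
  dte <- gq_condition_te(gq, st$samples, "ctrl", "treat")
  hl2 <- merge(hl, dte, by = "transcript_id")
  hl2 <- hl2[is.finite(hl2$dte_log2)]
  med <- tapply(hl2$dte_log2, hl2$group, median)
  expect_gt(med[["high_UTR"]], med[["low_UTR"]])
  tt <- compare_groups(hl2$dte_log2, hl2$group, test = "t_test")
  expect_lt(tt$p_value, 0.01)
})
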