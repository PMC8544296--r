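#' 5'UTR ribosome occupancy index
#'
#' The 5'UTR index of a transcript is the fraction of its RPF reads whose
#' P-site falls in the 5'UTR: `utr5_reads / total_reads` on that transcript.
#' Following the selection rule of the analysis, only transcripts with
#' `utr5_reads > 0` are returned; transcripts with zero total reads are
#' skipped with a notice. Replicates may be pooled to condition level by
#' passing a sample sheet.
#'
#' @param rc region counts ([region_counts()]); only the `rpf` library rows
#'   are used.
#' @param samples optional sample sheet (`sample_id`, `condition`). When
#'   given, counts are pooled within condition and the output unit column is
#'   `condition`; otherwise per-sample records are returned.
#' @return `data.table`: `transcript_id`, `sample_id` or `condition`,
#'   `utr5_reads`, `total_reads`, `utr5_index` in (0, 1].
#' @export
utr5_index <- function(rc, samples = NULL) {
  rc <- as.data.table(rc)[library == "rpf"]
  if (nrow(rc) == 0L) stop("no RPF region counts")
  if (!is.null(samples)) {
    samples <- as.data.table(samples)
    rc <- samples[, .(sample_id, condition)][rc, on = "sample_id", nomatch = 0L]
    rc <- rc[, .(n_utr5 = sum(n_utr5), n_total = sum(n_total)),
             by = .(transcript_id, condition)]
    unit <- "condition"
  } else {
    rc <- rc[, .(transcript_id, sample_id, n_utr5, n_total)]
    unit <- "sample_id"
  }
  n_zero <- sum(rc$n_total == 0L)
  if (n_zero > 0L) message(n_zero, " transcript record(s) with zero reads skipped")
  rc <- rc[n_total > 0L]
  out <- rc[n_utr5 > 0L,
            setNames(.(transcript_id, get(unit), n_utr5, n_total,
                       n_utr5 / n_total),
                     c("transcript_id", unit, "utr5_reads", "total_reads",
                       "utr5_index"))]
  setorderv(out, c("transcript_id", unit))
  out[]
}

#' Change in 5'UTR index between conditions
#'
#' Pools replicates per condition and returns, per transcript, the 5'UTR
#' index in each condition and its difference (treatment - control). Only
#' transcripts with 5'UTR reads > 0 in both conditions are comparable and
#' returned.
#'
#' @param rc region counts (rpf library).
#' @param samples sample sheet with `sample_id`, `condition`.
#' @param control,treatment condition labels.
#' @export
delta_utr5_index <- function(rc, samples, control, treatment) {
  idx <- utr5_index(rc, samples = samples)
  a <- idx[condition == control,
           .(transcript_id, index_ctrl = utr5_index, utr5_ctrl = utr5_reads)]
  b <- idx[condition == treatment,
           .(transcript_id, index_treat = utr5_index, utr5_treat = utr5_reads)]
  out <- a[b, on = "transcript_id", nomatch = 0L]
  out[, delta_index := index_treat - index_ctrl]
  setorder(out, transcript_id)
  out[]
}

#' Split transcripts into high_UTR / low_UTR halves
#'
#' Orders records by 5'UTR index (ties broken by transcript id for
#' determinism) and assigns the lower `ceiling(n/2)` to `low_UTR` and the
#' rest to `high_UTR`: a median split whose group sizes differ by at most 1,
#' with records at the median going to `low_UTR`.
#'
#' @param records output of [utr5_index()] (one record per transcript).
#' @return the records with a `group` column (`"low_UTR"`/`"high_UTR"`).
#' @export
split_high_low <- function(records) {
  records <- as.data.table(records)
  if (nrow(records) < 2L) stop("need at least 2 records to split")
  if (anyDuplicated(records$transcript_id))
    stop("records must contain one row per transcript")
  if (length(unique(records$utr5_index)) == 1L)
    stop("all 5'UTR indices identical: no meaningful high/low split")
  ord <- order(records$utr5_index, records$transcript_id)
  n_low <- ceiling(nrow(records) / 2)
  grp <- character(nrow(records))
  grp[ord] <- rep(c("low_UTR", "high_UTR"),
                  c(n_low, nrow(records) - n_low))
  records[, group := grp]
  records[]
}

#' Compare groups of values with a classical test
#'
#' One-way ANOVA across k groups (classical equal-variance F test), the
#' two-sample t-test (equal-variance by default to match the classical test;
#' Welch via `var_equal = FALSE`), or the Mann-Whitney U test. Degenerate
#' input in which every value is identical has no within-group variance; the
#' result is flagged and the p-value is `NA`.
#'
#' @param values numeric vector.
#' @param groups group labels, same length.
#' @param test `"anova"`, `"t_test"` or `"mannwhitney"`.
#' @param var_equal classical pooled-variance tests when `TRUE` (default).
#' @return list with `method`, `statistic`, `p_value`, `df`, `degenerate`.
#' @export
compare_groups <- function(values, groups,
                           test = c("anova", "t_test", "mannwhitney"),
                           var_equal = TRUE) {
  test <- match.arg(test)
  keep <- is.finite(values) & !is.na(groups)   # NA/Inf carry no information
  values <- values[keep]; groups <- as.character(groups[keep])
  ng <- table(groups)
  if (length(ng) < 2L) stop("need at least 2 non-empty groups")
  if (test %in% c("anova", "t_test") && any(ng < 2L))
    stop("variance-based tests need >= 2 values per group")
  if (test == "t_test" && length(ng) != 2L)
    stop("t-test requires exactly 2 groups")
  degenerate <- length(unique(values)) == 1L
  if (degenerate && test != "mannwhitney") {
    return(list(method = test, statistic = NA_real_, p_value = NA_real_,
                df = NA_real_, degenerate = TRUE))
  }
  g <- factor(groups)
  res <- switch(test,
    anova = {
      ft <- oneway.test(values ~ g, var.equal = var_equal)
      list(statistic = unname(ft$statistic), p_value = ft$p.value,
           df = unname(ft$parameter))
    },
    t_test = {
      lv <- levels(g)
      tt <- t.test(values[g == lv[1L]], values[g == lv[2L]],
                   var.equal = var_equal)
      list(statistic = unname(tt$statistic), p_value = tt$p.value,
           df = unname(tt$parameter))
    },
    mannwhitney = {
      wt <- suppressWarnings(wilcox.test(values[g == levels(g)[1L]],
                                         values[g == levels(g)[2L]]))
      list(statistic = unname(wt$statistic), p_value = wt$p.value,
           df = NA_real_)
    })
  c(list(method = test), res, list(degenerate = degenerate))
}
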