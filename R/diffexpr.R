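#' Classify genes as up / unchanged / down between two conditions
#'
#' Works on the gene x sample table from [gene_quant()] at one of three
#' levels: `"rna"` (whole-transcript FPKM, transcriptional), `"ribo"`
#' (CDS-restricted RPKM, translational) or `"te"` (translation efficiency).
#' Replicates are quantified independently and condition values are the mean
#' across replicates. The fold change is
#' `log2((mean_treat + pc) / (mean_ctrl + pc))` with pseudocount `pc`
#' (default 0.5) for the count-derived levels; for TE the ratio of condition
#' mean TEs is used without pseudocount (TE is already a ratio and is
#' undefined, rather than zero, at low expression).
#'
#' A gene is `up` when `log2fc >= theta`, `down` when `log2fc <= -theta`,
#' otherwise `unchanged`. Genes failing the expression floor in *both*
#' conditions (for TE: undefined in either condition) are reported as
#' `not_assessed`, never silently dropped and never counted as unchanged.
#'
#' @param gq gene quantification table ([gene_quant()]).
#' @param samples sample sheet: `sample_id`, `condition` (and anything else).
#' @param control,treatment condition labels.
#' @param level `"rna"`, `"ribo"` or `"te"`.
#' @param theta absolute log2 fold-change threshold (default 1, i.e. 2-fold).
#' @param floor expression floor: a gene is assessed when its condition mean
#'   exceeds `floor` in at least one condition (default 1 FPKM/RPKM).
#' @param pseudocount added to condition means before the ratio (rna/ribo).
#' @param add_pvalue optional two-sample t-test on `log2(value + pseudocount)`
#'   across replicates (volcano-style output; never gates the class).
#' @return `data.table`: `gene_id`, `level`, `mean_ctrl`, `mean_treat`,
#'   `log2fc`, `passed_floor`, `class` (and `p_value` if requested).
#' @export
classify_genes <- function(gq, samples, control, treatment,
                           level = c("ribo", "rna", "te"),
                           theta = 1, floor = 1, pseudocount = 0.5,
                           add_pvalue = FALSE) {
  level <- match.arg(level)
  gq <- as.data.table(gq)
  samples <- as.data.table(samples)
  for (cond in c(control, treatment))
    if (!cond %in% samples$condition) stop("condition not in sample sheet: ", cond)
  vcol <- switch(level, rna = "rna_fpkm", ribo = "ribo_rpkm", te = "te")
  x <- samples[, .(sample_id, condition)][gq, on = "sample_id", nomatch = 0L]
  x <- x[condition %in% c(control, treatment)]
  if (nrow(x) == 0L) stop("no samples for the requested conditions")
  x[, value := get(vcol)]
  cm <- x[, .(m = mean(value, na.rm = TRUE), n_def = sum(!is.na(value))),
          by = .(gene_id, condition)]
  cm[n_def == 0L, m := NA_real_]
  w <- dcast(cm, gene_id ~ condition, value.var = "m")
  setnames(w, c(control, treatment), c("mean_ctrl", "mean_treat"))

  if (level == "te") {
    w[, passed_floor := !is.na(mean_ctrl) & !is.na(mean_treat)]
    w[, log2fc := ifelse(passed_floor, log2(mean_treat / mean_ctrl), NA_real_)]
  } else {
    w[, passed_floor := (!is.na(mean_ctrl) & mean_ctrl >= floor) |
                        (!is.na(mean_treat) & mean_treat >= floor)]
    w[, log2fc := log2((mean_treat + pseudocount) / (mean_ctrl + pseudocount))]
  }
  w[, class := fifelse(!passed_floor, "not_assessed",
               fifelse(log2fc >= theta, "up",
               fifelse(log2fc <= -theta, "down", "unchanged")))]
  w[, level := level]
  if (add_pvalue) {
    pv <- x[, .(p_value = tryCatch({
      a <- log2(value[condition == control] + pseudocount)
      b <- log2(value[condition == treatment] + pseudocount)
      stats::t.test(b, a, var.equal = TRUE)$p.value
    }, error = function(e) NA_real_)), by = gene_id]
    w <- pv[w, on = "gene_id"]
  }
  setcolorder(w, c("gene_id", "level", "mean_ctrl", "mean_treat",
                   "log2fc", "passed_floor", "class"))
  setorder(w, gene_id)
  w[]
}

#' Summarise a classification
#'
#' Up/down/unchanged/not-assessed counts per level, as used in the pipeline's
#' summary JSON.
#' @param calls one or more stacked outputs of [classify_genes()].
#' @export
classification_summary <- function(calls) {
  as.data.table(calls)[, .N, by = .(level, class)][order(level, class)]
}

#' Log2 change in translation efficiency
#'
#' `log2(te_treat / te_ctrl)`; undefined (NA) TE propagates. Equal to the
#' difference of the ribo and rna log2 fold changes when all four densities
#' are defined.
#'
#' @param te_treat,te_ctrl translation efficiencies (vectorised).
#' @export
te_change <- function(te_treat, te_ctrl) {
  ifelse(is.na(te_treat) | is.na(te_ctrl), NA_real_, log2(te_treat / te_ctrl))
}
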