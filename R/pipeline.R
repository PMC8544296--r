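#' Run the full analysis pipeline
#'
#' Orchestrates annotation -> quantification -> differential classification
#' -> 5'UTR-index group analysis -> uORF detection and shift scoring ->
#' (optional) over-representation analysis, writing every table as TSV plus
#' a machine-readable `summary.json` and a short human-readable
#' `report.txt` under `out_dir`. Stage failures are logged with the stage
#' name, a `FAILED` marker file is written next to any partial outputs, and
#' the error is re-raised.
#'
#' The config is a list (or a YAML file parsed into one) with entries:
#' \describe{
#'   \item{annotation}{BED12 path (`annotation_format: "gtf"` to switch).}
#'   \item{fasta}{transcript FASTA (optional; required for uORF detection).}
#'   \item{samples}{sample sheet: a data.frame/list of records with
#'     `sample_id`, `condition`, `replicate`, and per-library alignment
#'     paths `rpf` and `rna`.}
#'   \item{control_condition, treatment_condition}{condition labels
#'     (defaults `"ctrl"`, `"treat"`).}
#'   \item{gene_sets}{optional GMT path; enables enrichment of the up- and
#'     down-regulated translational gene lists against the universe of genes
#'     with defined TE.}
#'   \item{params}{optional overrides: `min_read_length` (20),
#'     `psite_offset` (12), `offsets_by_length` (named list), `te_floor`
#'     (1), `log2fc_threshold` (1), `pseudocount` (0.5),
#'     `shift_pseudocount` (1), `seed` (1).}
#' }
#'
#' @param config list or path to a YAML file.
#' @param out_dir output directory (created).
#' @return invisibly, the summary list.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    message(msg)
    cat(msg, "\n", file = log_path, append = TRUE)
  }
  stage <- "config"
  on_fail <- function(e) {
    writeLines(paste0("stage: ", stage, "\n", conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  }
  tryCatch({
    prm <- modifyList(list(
      min_read_length = 20L, psite_offset = 12L, offsets_by_length = list(),
      te_floor = 1, log2fc_threshold = 1, pseudocount = 0.5,
      shift_pseudocount = 1, seed = 1L), config$params %||% list())
    set.seed(prm$seed)
    control <- config$control_condition %||% "ctrl"
    treatment <- config$treatment_condition %||% "treat"
    samples <- rbindlist(lapply(config$samples, as.list), fill = TRUE)
    if (is.data.frame(config$samples)) samples <- as.data.table(config$samples)
    req <- c("sample_id", "condition", "rpf", "rna")
    miss <- setdiff(req, names(samples))
    if (length(miss)) stop("sample sheet lacks: ", paste(miss, collapse = ", "))
    for (p in c(samples$rpf, samples$rna))
      if (!file.exists(p)) stop("alignment file not found: ", p)
    offs <- psite_offsets(default = prm$psite_offset,
                          by_length = unlist(prm$offsets_by_length))

    stage <- "annotation"
    logf("reading annotation: ", config$annotation)
    models <- read_annotation(config$annotation,
                              format = config$annotation_format %||% "bed12")
    if (!is.null(config$fasta)) models <- attach_sequences(models, config$fasta)

    stage <- "quant"
    logf("reading alignments for ", nrow(samples), " samples")
    aln <- rbindlist(lapply(seq_len(nrow(samples)), function(i) rbind(
      read_alignments(samples$rpf[i], samples$sample_id[i], "rpf"),
      read_alignments(samples$rna[i], samples$sample_id[i], "rna"))))
    aln <- filter_reads(aln, min_len = prm$min_read_length)
    aln <- assign_psites(aln, models, offs)
    rc <- region_counts(aln, models, offs)
    fwrite(rc, file.path(out_dir, "region_counts.tsv"), sep = "\t")
    regd <- region_distribution(aln, models, offs)
    frd <- frame_distribution(aln, models, offs)
    lh <- length_histogram(aln[library == "rpf"])
    fwrite(lh, file.path(out_dir, "rpf_length_histogram.tsv"), sep = "\t")
    gq <- gene_quant(rc, models, te_floor = prm$te_floor)
    fwrite(gq, file.path(out_dir, "gene_quant.tsv"), sep = "\t")

    stage <- "diffexpr"
    calls <- rbindlist(lapply(c("rna", "ribo", "te"), function(lv)
      classify_genes(gq, samples, control, treatment, level = lv,
                     theta = prm$log2fc_threshold, floor = prm$te_floor,
                     pseudocount = prm$pseudocount)), use.names = TRUE)
    fwrite(calls, file.path(out_dir, "diff_calls.tsv"), sep = "\t")
    csum <- classification_summary(calls)

    stage <- "utrgroups"
    idx_ctrl <- utr5_index(rc[sample_id %in%
                                samples[condition == control, sample_id]],
                           samples = samples)
    didx <- delta_utr5_index(rc, samples, control, treatment)
    fwrite(didx, file.path(out_dir, "utr5_index.tsv"), sep = "\t")
    te_calls <- calls[level == "te"]
    tx2g <- models[, .(transcript_id, gene_id)]
    didx_g <- tx2g[didx, on = "transcript_id", nomatch = NULL]
    grp <- te_calls[, .(gene_id, class)][didx_g, on = "gene_id", nomatch = NULL]
    anova_res <- if (length(unique(grp[class %in% c("up", "unchanged", "down"), class])) >= 2L)
      compare_groups(grp[class %in% c("up", "unchanged", "down"), delta_index],
                     grp[class %in% c("up", "unchanged", "down"), class],
                     test = "anova")
    else list(method = "anova", statistic = NA_real_, p_value = NA_real_,
              df = NA_real_, degenerate = TRUE)
    hl <- tryCatch(split_high_low(idx_ctrl), error = function(e) NULL)
    ttest_res <- list(method = "t_test", statistic = NA_real_,
                      p_value = NA_real_, df = NA_real_, degenerate = TRUE)
    if (!is.null(hl)) {
      dte <- gq_condition_te(gq, samples, control, treatment)
      hl2 <- dte[hl, on = "transcript_id", nomatch = NULL]
      hl2 <- hl2[!is.na(dte_log2)]
      fwrite(hl2, file.path(out_dir, "utr_groups.tsv"), sep = "\t")
      if (all(table(hl2$group) >= 2L))
        ttest_res <- compare_groups(hl2$dte_log2, hl2$group, test = "t_test")
    }

    stage <- "uorf"
    uorfs <- NULL
    if (!all(is.na(models$sequence))) {
      uorfs <- find_uorfs(models)
      fwrite(uorfs, file.path(out_dir, "uorfs.tsv"), sep = "\t")
    }
    rc_ctrl <- rc[sample_id %in% samples[condition == control, sample_id]]
    rc_treat <- rc[sample_id %in% samples[condition == treatment, sample_id]]
    shifts <- shift_score(rc_ctrl, rc_treat, pseudocount = prm$shift_pseudocount)
    fwrite(shifts, file.path(out_dir, "shift_scores.tsv"), sep = "\t")

    stage <- "enrichment"
    enr <- list()
    if (!is.null(config$gene_sets)) {
      sets <- read_gmt(config$gene_sets)
      universe <- calls[level == "te" & passed_floor == TRUE, gene_id]
      for (dir_lab in c("up", "down")) {
        qy <- calls[level == "ribo" & class == dir_lab, gene_id]
        if (length(intersect(qy, universe))) {
          res <- ora(qy, sets, universe)
          fwrite(res, file.path(out_dir, sprintf("enrichment_%s.tsv", dir_lab)),
                 sep = "\t")
          enr[[dir_lab]] <- nrow(res[fdr <= 0.05])
        }
      }
    }

    stage <- "report"
    summary <- list(
      n_transcripts = nrow(models),
      n_samples = nrow(samples),
      rpf_region_pct = if (nrow(regd)) as.list(setNames(regd$pct, regd$region)) else NULL,
      rpf_frame_pct = if (nrow(frd)) as.list(setNames(frd$pct, paste0("frame", frd$frame))) else NULL,
      class_counts = split(csum$N, paste(csum$level, csum$class, sep = "_")),
      utr5_index_anova = anova_res[c("statistic", "p_value")],
      high_low_utr_ttest = ttest_res[c("statistic", "p_value")],
      n_uorfs = if (is.null(uorfs)) NULL else nrow(uorfs),
      n_shift_scored = nrow(shifts),
      enrichment_sets_q05 = if (length(enr)) enr else NULL,
      seed = prm$seed)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    writeLines(render_report(summary), file.path(out_dir, "report.txt"))
    logf("pipeline complete: ", out_dir)
    invisible(summary)
  }, error = on_fail)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Condition-level TE change per transcript
#'
#' Averages per-replicate TE within each condition and returns, per gene /
#' transcript, the two condition TEs and their log2 change
#' ([te_change()]). Undefined TE in any replicate of a condition propagates.
#'
#' @param gq gene quantification table ([gene_quant()]).
#' @param samples sample sheet with `sample_id`, `condition`.
#' @param control,treatment condition labels.
#' @return `data.table`: `gene_id`, `transcript_id`, `te_ctrl`, `te_treat`,
#'   `dte_log2`.
#' @export
gq_condition_te <- function(gq, samples, control, treatment) {
  samples <- as.data.table(samples)
  x <- samples[, .(sample_id, condition)][as.data.table(gq),
                                          on = "sample_id", nomatch = 0L]
  cm <- x[condition %in% c(control, treatment),
          .(te = mean(te, na.rm = FALSE)), by = .(gene_id, transcript_id, condition)]
  w <- dcast(cm, gene_id + transcript_id ~ condition, value.var = "te")
  setnames(w, c(control, treatment), c("te_ctrl", "te_treat"))
  w[, dte_log2 := te_change(te_treat, te_ctrl)]
  w[]
}

render_report <- function(s) {
  fmt_pct <- function(x) if (is.null(x)) "n/a" else
    paste(sprintf("%s %.1f%%", names(x), unlist(x)), collapse = ", ")
  c("Translatome remodeling analysis summary",
    "=======================================",
    sprintf("Transcripts: %d   Samples: %d   Seed: %d",
            s$n_transcripts, s$n_samples, s$seed),
    sprintf("RPF region occupancy: %s", fmt_pct(s$rpf_region_pct)),
    sprintf("RPF frame occupancy:  %s", fmt_pct(s$rpf_frame_pct)),
    "Differential classes:",
    paste(sprintf("  %s: %d", names(s$class_counts),
                  unlist(s$class_counts)), collapse = "\n"),
    sprintf("5'UTR-index change across TE classes (one-way ANOVA): F = %.3g, p = %.3g",
            s$utr5_index_anova$statistic %||% NA,
            s$utr5_index_anova$p_value %||% NA),
    sprintf("Delta TE, high_UTR vs low_UTR (t-test): t = %.3g, p = %.3g",
            s$high_low_utr_ttest$statistic %||% NA,
            s$high_low_utr_ttest$p_value %||% NA),
    if (!is.null(s$n_uorfs)) sprintf("uORFs detected: %d", s$n_uorfs) else NULL,
    sprintf("Transcripts with CDS:5'UTR shift score: %d", s$n_shift_scored))
}

#' Relative expression by the 2^-ddCt method
#'
#' Standard relative qPCR quantification: the target gene's Ct is normalised
#' to a reference gene within each condition, and the treatment is expressed
#' relative to control:
#' `2^-((ct_target_treat - ct_ref_treat) - (ct_target_ctrl - ct_ref_ctrl))`.
#'
#' @param ct_target_treat,ct_ref_treat,ct_target_ctrl,ct_ref_ctrl cycle
#'   thresholds (vectorised).
#' @export
ddct <- function(ct_target_treat, ct_ref_treat, ct_target_ctrl, ct_ref_ctrl) {
  stopifnot(all(is.finite(c(ct_target_treat, ct_ref_treat,
                            ct_target_ctrl, ct_ref_ctrl))))
  2^-((ct_target_treat - ct_ref_treat) - (ct_target_ctrl - ct_ref_ctrl))
}
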