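#!/usr/bin/env Rscript
# 5'UTR-index analysis of the uORF-shift study: the index change across TE
# classes (one-way ANOVA) and the TE change between high_UTR and low_UTR
# halves (two-sample t-test). Writes results/tables/utr_groups.tsv.

suppressMessages({library(riboshift); library(data.table)})
d <- "results/data/shift"
models <- read_annotation(file.path(d, "annotation.bed"))
samples <- fread(file.path(d, "samples.tsv"))
aln <- rbindlist(lapply(samples$sample_id, function(s) rbind(
  read_alignments(file.path(d, paste0(s, "_rpf.tsv")), s, "rpf"),
  read_alignments(file.path(d, paste0(s, "_rna.tsv")), s, "rna"))))
aln <- assign_psites(filter_reads(aln), models)
rc <- region_counts(aln, models)
gq <- gene_quant(rc, models)

didx <- delta_utr5_index(rc, samples, "ctrl", "treat")
calls_te <- classify_genes(gq, samples, "ctrl", "treat", level = "te")
tx2g <- models[, .(transcript_id, gene_id)]
dg <- merge(merge(didx, tx2g, by = "transcript_id"),
            calls_te[, .(gene_id, class)], by = "gene_id")
dg <- dg[class %in% c("up", "unchanged", "down")]
av <- compare_groups(dg$delta_index, dg$class, test = "anova")
cat(sprintf("5'UTR-index change by TE class (n=%d): F = %.2f, p = %.3g\n",
            nrow(dg), av$statistic, av$p_value))
print(dg[, .(mean_delta_index = mean(delta_index), .N), by = class])

ctrl <- samples[condition == "ctrl", sample_id]
idx_ctrl <- utr5_index(rc[sample_id %in% ctrl], samples = samples)
hl <- split_high_low(idx_ctrl)
dte <- merge(hl, gq_condition_te(gq, samples, "ctrl", "treat"),
             by = "transcript_id")
dte <- dte[is.finite(dte_log2)]
fwrite(dte, "results/tables/utr_groups.tsv", sep = "\t")
tt <- compare_groups(dte$dte_log2, dte$group, test = "t_test")
med <- dte[, .(median_delta_te_log2 = median(dte_log2)), by = group]
print(med)
cat(sprintf("high_UTR vs low_UTR TE change: t = %.2f, p = %.3g\n",
            tt$statistic, tt$p_value))
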