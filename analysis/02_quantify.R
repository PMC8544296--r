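#!/usr/bin/env Rscript
# Quantify the main study: length filter, P-site assignment, region/frame
# occupancy, per-transcript region counts and per-gene RNA FPKM / Ribo RPKM /
# TE. Writes results/tables/{region_counts,gene_quant,region_frame}.tsv.

suppressMessages({library(riboshift); library(data.table)})
d <- "results/data/main"
dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)

models <- attach_sequences(read_annotation(file.path(d, "annotation.bed")),
                           file.path(d, "transcripts.fa"))
samples <- fread(file.path(d, "samples.tsv"))
aln <- rbindlist(lapply(samples$sample_id, function(s) rbind(
  read_alignments(file.path(d, paste0(s, "_rpf.tsv")), s, "rpf"),
  read_alignments(file.path(d, paste0(s, "_rna.tsv")), s, "rna"))))

aln <- assign_psites(filter_reads(aln, min_len = 20L), models)
rc <- region_counts(aln, models)
gq <- gene_quant(rc, models)
fwrite(rc, "results/tables/region_counts.tsv", sep = "\t")
fwrite(gq, "results/tables/gene_quant.tsv", sep = "\t")

ctrl <- samples[condition == "ctrl", sample_id]
regd <- region_distribution(aln[sample_id %in% ctrl], models)
frd <- frame_distribution(aln[sample_id %in% ctrl], models)
fwrite(rbind(regd[, .(what = paste0("region_", region), pct)],
             frd[, .(what = paste0("frame_", frame), pct)]),
       "results/tables/region_frame.tsv", sep = "\t")

lh <- length_histogram(aln[library == "rpf"])
cat(sprintf("RPF modal length: %d nt\n", lh$read_length[which.max(lh$n)]))
cat(sprintf("Control occupancy: 5'UTR %.1f%%, CDS %.1f%%, 3'UTR %.1f%%\n",
            regd[region == "utr5", pct], regd[region == "cds", pct],
            regd[region == "utr3", pct]))
cat(sprintf("Control in-frame (frame 0): %.1f%%\n", frd[frame == 0, pct]))
cat(sprintf("Genes with defined TE in every sample: %d / %d\n",
            gq[, .(ok = all(!is.na(te))), by = gene_id][, sum(ok)],
            uniqueN(gq$gene_id)))
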