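#!/usr/bin/env Rscript
# Over-representation analysis of the main study's translationally up- and
# down-regulated gene lists against synthetic gene-set collections: one set
# spiked with translationally induced genes (which should enrich) and random
# sets (which should not). Writes results/tables/enrichment.tsv.

suppressMessages({library(riboshift); library(data.table)})
calls <- fread("results/tables/diff_calls.tsv")
truth <- fread("results/data/main/truth.tsv")

universe <- calls[level == "te" & passed_floor == TRUE, gene_id]
set.seed(103)
sets <- c(
  list(spiked_te_up = c(sample(truth[group == "te_up", gene_id], 40),
                        sample(universe, 40))),
  lapply(setNames(1:10, sprintf("random%02d", 1:10)),
         function(i) sample(universe, 80)))

res <- rbindlist(lapply(c("up", "down"), function(dir_lab) {
  qy <- calls[level == "ribo" & class == dir_lab, gene_id]
  cbind(direction = dir_lab, ora(qy, sets, universe))
}))
fwrite(res, "results/tables/enrichment.tsv", sep = "\t")
print(res[direction == "up"][1:4, .(set_id, k, K, p = signif(p, 3),
                                    fdr = signif(fdr, 3))])
cat(sprintf("spiked set FDR in the up list: %.3g; random sets significant: %d\n",
            res[direction == "up" & set_id == "spiked_te_up", fdr],
            res[set_id != "spiked_te_up", sum(fdr <= 0.05)]))
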