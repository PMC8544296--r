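#!/usr/bin/env Rscript
# Generate the synthetic study the downstream steps analyse.
#
# Two designs are written under results/data/:
#   main/  - 1,000 genes, 2 conditions x 2 replicates; 100 genes up and 100
#            down at each of the transcription and translation levels
#            (|log2FC| = 2), 30% of genes carrying uORFs.
#   shift/ - 1,000 genes of which 500 carry uORFs whose 5'UTR occupancy
#            collapses from 0.40 to 0.10 under treatment (uORF bypass), the
#            other 500 uORF-free nulls.
# Depth here is 5e5 reads/library so the written TSVs stay desk-sized; the
# package defaults (2e6) are used by the in-memory acceptance checks.

suppressMessages({library(riboshift); library(data.table)})
seed <- 101L
out <- "results/data"

main_cfg <- sim_config(n_genes = 1000, reads_per_library = 5e5,
                       n_rna_up = 100, n_rna_down = 100,
                       n_te_up = 100, n_te_down = 100, seed = seed)
main <- simulate_study(main_cfg)
write_simulation(main, file.path(out, "main"), sam = FALSE)

shift_cfg <- sim_config(n_genes = 1000, reads_per_library = 2e5,
                        uorf_fraction = 0.5, n_uorf_shift = 500,
                        seed = seed + 1L)
shift <- simulate_study(shift_cfg)
write_simulation(shift, file.path(out, "shift"), sam = FALSE)

for (nm in c("main", "shift")) {
  st <- get(nm)
  cat(sprintf("[%s] %d transcripts, %d samples, %d reads/library\n",
              nm, nrow(st$models), nrow(st$samples),
              st$config$reads_per_library))
  print(st$truth[, .N, by = group][order(-N)])
}
cat("written under", out, "\n")
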