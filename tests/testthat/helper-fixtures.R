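# Shared simulated fixtures, built once per test run and cached. All are
# generated in code under fixed seeds; nothing is read from disk.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# A small mixed study: transcription-, translation- and uORF-shift effects.
small_study <- function() fixture("small_study", function() {
  simulate_study(sim_config(
    n_genes = 60, reads_per_library = 3e4,
    n_rna_up = 5, n_rna_down = 5, n_te_up = 5, n_te_down = 5,
    n_uorf_shift = 10, seed = 7))
})

small_quant <- function() fixture("small_quant", function() {
  st <- small_study()
  aln <- assign_psites(filter_reads(st$alignments), st$models)
  rc <- region_counts(aln, st$models)
  list(study = st, aln = aln, rc = rc, gq = gene_quant(rc, st$models))
})

# Homogeneous-occupancy study for region/frame mixture recovery.
uniform_occ_study <- function() fixture("uniform_occ_study", function() {
  simulate_study(sim_config(
    n_genes = 100, reads_per_library = 1e5, uorf_fraction = 0,
    base_utr5_occ = 0.07, utr3_occ = 0.03,
    frame_probs = c(0.75, 0.15, 0.10),
    n_reps = 1, seed = 31))
})
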