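#' Simulation configuration
#'
#' Defines a synthetic two-condition (optionally three, with an antioxidant
#' "reversal" arm) ribosome-profiling study: a transcriptome with planted
#' uORFs, and paired RPF/RNA libraries with negative-binomial count noise and
#' known per-gene truth. Defaults emulate a typical short-read mammalian
#' Ribo-seq design: ~30-nt footprints concentrated on the CDS
#' (5'UTR/CDS/3'UTR occupancy 6.5/90.9/2.6%), 74.9% of CDS P-sites in frame
#' 0, two replicates per condition, and 2M reads per library.
#'
#' Per-gene expected counts are `abundance x transcript length` (RNA) and
#' `abundance x TE x CDS length` (RPF); realised counts are gamma-Poisson
#' (negative binomial, dispersion `nb_dispersion`) with the library total
#' kept exact by multinomial allocation. Genes carrying a uORF have elevated
#' 5'UTR occupancy and a Kozak-class-dependent baseline TE penalty (stronger
#' uAUG context, stronger repression of the main ORF). `uorf_shift` genes
#' additionally move 5'UTR ribosome density into the CDS under treatment
#' (`shift_utr5_occ`, control -> treatment), the uORF-bypass signature.
#'
#' @param n_genes number of genes (one transcript each).
#' @param seed integer; fixes transcriptome, truth and reads bit-for-bit.
#' @param utr5_meanlog,utr5_sdlog,utr5_min 5'UTR length distribution
#'   (lognormal, nt, truncated below).
#' @param cds_meanlog,cds_sdlog,cds_min CDS length distribution (rounded to a
#'   multiple of 3; AUG...stop).
#' @param utr3_meanlog,utr3_sdlog,utr3_min 3'UTR length distribution.
#' @param abundance_sdlog lognormal sd of gene abundance.
#' @param te_sdlog lognormal sd of baseline TE (TE spans roughly two orders
#'   of magnitude in mammalian cells).
#' @param uorf_fraction fraction of genes carrying a planted uORF.
#' @param kozak_mix probabilities of strong/adequate/weak planted contexts.
#' @param uorf_te_mult baseline-TE multiplier per Kozak class (repression).
#' @param n_rna_up,n_rna_down,rna_effect transcription-level effect genes and
#'   their |log2 fold change| under treatment.
#' @param n_te_up,n_te_down,te_effect translation-level effect genes (change
#'   ribosome loading, not mRNA).
#' @param n_uorf_shift number of uORF genes whose 5'UTR occupancy shifts.
#' @param shift_utr5_occ length-2 numeric: 5'UTR occupancy of shift genes in
#'   control and treatment.
#' @param base_utr5_occ,uorf_utr5_occ,utr3_occ RPF region occupancies for
#'   genes without / with a uORF, and the 3'UTR occupancy.
#' @param frame_probs P-site frame probabilities within the CDS (frame 0 is
#'   the annotated frame).
#' @param rpf_lengths,rpf_length_probs RPF length distribution (modal 30 nt).
#' @param rna_read_length RNA-seq read length (uniform placement).
#' @param reads_per_library exact reads emitted per sample x library.
#' @param nb_dispersion negative-binomial dispersion of gene counts.
#' @param n_reps replicates per condition.
#' @param conditions condition labels; `"ctrl"` and `"treat"` are required,
#'   `"nac"` adds the reversal arm.
#' @param nac_reversal fraction of every treatment effect reversed toward
#'   control in the `"nac"` arm (0.9 = effects shrunk to 10%).
#' @param psite_offset P-site offset used for read placement (and expected
#'   by quantification).
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_genes = 1000L, seed = 1L,
                       utr5_meanlog = log(150), utr5_sdlog = 0.35, utr5_min = 24L,
                       cds_meanlog = log(1200), cds_sdlog = 0.45, cds_min = 120L,
                       utr3_meanlog = log(400), utr3_sdlog = 0.45, utr3_min = 60L,
                       abundance_sdlog = 1, te_sdlog = 1,
                       uorf_fraction = 0.3,
                       kozak_mix = c(strong = 1/3, adequate = 1/3, weak = 1/3),
                       uorf_te_mult = c(strong = 0.5, adequate = 0.7, weak = 0.9),
                       n_rna_up = 0L, n_rna_down = 0L, rna_effect = 2,
                       n_te_up = 0L, n_te_down = 0L, te_effect = 2,
                       n_uorf_shift = 0L, shift_utr5_occ = c(0.4, 0.1),
                       base_utr5_occ = 0.065, uorf_utr5_occ = 0.25,
                       utr3_occ = 0.026,
                       frame_probs = c(0.749, 0.150, 0.101),
                       rpf_lengths = 26:34,
                       rpf_length_probs = c(0.02, 0.05, 0.10, 0.16, 0.34,
                                            0.16, 0.10, 0.05, 0.02),
                       rna_read_length = 50L,
                       reads_per_library = 2e6, nb_dispersion = 0.1,
                       n_reps = 2L, conditions = c("ctrl", "treat"),
                       nac_reversal = 0.9, psite_offset = 12L) {
  cfg <- as.list(environment())
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    stopifnot(n_genes >= 1L, n_reps >= 1L, reads_per_library >= 1,
              nb_dispersion > 0, psite_offset >= 0L)
    if (!all(c("ctrl", "treat") %in% conditions))
      stop("conditions must include 'ctrl' and 'treat'")
    if (!all(conditions %in% c("ctrl", "treat", "nac")))
      stop("unknown condition label; allowed: ctrl, treat, nac")
    occ <- c(base_utr5_occ, uorf_utr5_occ, utr3_occ, shift_utr5_occ,
             uorf_fraction)
    if (any(occ < 0 | occ > 1)) stop("occupancies/fractions must be in [0,1]")
    if (any(c(base_utr5_occ, uorf_utr5_occ, shift_utr5_occ) + utr3_occ >= 1))
      stop("5'UTR + 3'UTR occupancy must leave CDS probability > 0")
    if (abs(sum(frame_probs) - 1) > 1e-8) stop("frame_probs must sum to 1")
    if (abs(sum(rpf_length_probs) - 1) > 1e-8)
      stop("rpf_length_probs must sum to 1")
    if (length(rpf_lengths) != length(rpf_length_probs))
      stop("rpf_lengths and rpf_length_probs differ in length")
    n_uorf <- max(round(uorf_fraction * n_genes), n_uorf_shift)
    if (n_uorf > n_genes) stop("more uORF genes requested than genes")
    if (n_rna_up + n_rna_down + n_te_up + n_te_down + n_uorf_shift > n_genes)
      stop("effect gene sets exceed n_genes (they must be disjoint)")
    if (utr5_min < 13L)
      stop("utr5_min must be >= 13 nt to host a planted uORF context ",
           "(the uORF cannot be longer than the 5'UTR)")
    if (utr5_min <= psite_offset)
      stop("utr5_min must exceed the P-site offset for 5'UTR placement")
    if (utr3_min < max(rpf_lengths) - psite_offset + 1L)
      stop("utr3_min too short for 3'UTR read placement at max RPF length")
  })
  structure(cfg, class = "sim_config")
}

#' Simulate a transcriptome with planted uORFs
#'
#' Draws transcript architectures and sequences under the config: CDS begins
#' AUG and ends with a stop codon (no internal in-frame stop), UTR sequence
#' is random, and each designated uORF gene gets an AUG planted at a recorded
#' 5'UTR position with the requested Kozak context. Also draws all per-gene
#' truth parameters (abundance, baseline TE, effect-group membership, region
#' occupancies per condition).
#'
#' @param cfg a [sim_config()].
#' @return list with `models` (transcript table with sequences) and `truth`
#'   (per-gene `data.table`: group labels, `true_rna_log2fc`,
#'   `true_te_log2fc` (intrinsic ribosome-loading fold), `expected_te_log2fc`
#'   (loading fold plus the CDS-share fold a 5'UTR->CDS occupancy shift
#'   induces in CDS-restricted TE), occupancies, uORF position and class).
#' @export
simulate_transcriptome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_genes
  rtrunc_len <- function(meanlog, sdlog, lo)
    pmax(as.integer(round(exp(rnorm(n, meanlog, sdlog)))), as.integer(lo))
  utr5_len <- rtrunc_len(cfg$utr5_meanlog, cfg$utr5_sdlog, cfg$utr5_min)
  cds_len <- rtrunc_len(cfg$cds_meanlog, cfg$cds_sdlog, cfg$cds_min)
  cds_len <- as.integer(3L * round(cds_len / 3))
  utr3_len <- rtrunc_len(cfg$utr3_meanlog, cfg$utr3_sdlog, cfg$utr3_min)

  gene_id <- sprintf("G%04d", seq_len(n))
  transcript_id <- sprintf("TX%04d", seq_len(n))

  # group assignment: uORF genes first, shift genes within them, then
  # disjoint rna/te effect genes among the non-shift genes
  n_uorf <- max(round(cfg$uorf_fraction * n), cfg$n_uorf_shift)
  uorf_idx <- sort(sample.int(n, n_uorf))
  shift_idx <- sort(sample(uorf_idx, cfg$n_uorf_shift))
  pool <- setdiff(seq_len(n), shift_idx)
  n_eff <- c(cfg$n_rna_up, cfg$n_rna_down, cfg$n_te_up, cfg$n_te_down)
  eff_idx <- sample(pool, sum(n_eff))
  splits <- rep(c("rna_up", "rna_down", "te_up", "te_down"), n_eff)
  group <- rep("null", n)
  group[shift_idx] <- "uorf_shift"
  group[eff_idx] <- splits

  kozak <- rep(NA_character_, n)
  kozak[uorf_idx] <- sample(names(cfg$kozak_mix), n_uorf, replace = TRUE,
                            prob = cfg$kozak_mix)

  abundance <- exp(rnorm(n, 0, cfg$abundance_sdlog))
  base_te <- exp(rnorm(n, 0, cfg$te_sdlog))
  base_te[uorf_idx] <- base_te[uorf_idx] * cfg$uorf_te_mult[kozak[uorf_idx]]

  true_rna_log2fc <- fifelse(group == "rna_up", cfg$rna_effect,
                     fifelse(group == "rna_down", -cfg$rna_effect, 0))
  true_te_log2fc <- fifelse(group == "te_up", cfg$te_effect,
                    fifelse(group == "te_down", -cfg$te_effect, 0))

  utr5_occ_ctrl <- fifelse(group == "uorf_shift", cfg$shift_utr5_occ[1L],
                   fifelse(seq_len(n) %in% uorf_idx, cfg$uorf_utr5_occ,
                           cfg$base_utr5_occ))
  utr5_occ_treat <- fifelse(group == "uorf_shift", cfg$shift_utr5_occ[2L],
                            utr5_occ_ctrl)

  # sequences
  bases <- c("A", "C", "G", "T")
  stops <- c("TAA", "TAG", "TGA")
  codons <- apply(expand.grid(bases, bases, bases), 1L, paste0, collapse = "")
  sense <- setdiff(codons, stops)
  uaug_pos <- rep(NA_integer_, n)
  seqs <- character(n)
  for (i in seq_len(n)) {
    utr5 <- paste(sample(bases, utr5_len[i], replace = TRUE), collapse = "")
    ncod <- cds_len[i] / 3L - 2L
    cds <- paste0("ATG",
                  paste(sample(sense, ncod, replace = TRUE), collapse = ""),
                  sample(stops, 1L))
    utr3 <- paste(sample(bases, utr3_len[i], replace = TRUE), collapse = "")
    if (i %in% uorf_idx) {
      planted <- plant_uorf(utr5, kozak[i])
      utr5 <- planted$seq
      uaug_pos[i] <- planted$pos
    }
    seqs[i] <- paste0(utr5, cds, utr3)
  }

  models <- data.table(
    transcript_id = transcript_id, gene_id = gene_id,
    length = utr5_len + cds_len + utr3_len,
    cds_start = utr5_len, cds_end = utr5_len + cds_len,
    sequence = seqs)
  models <- validate_transcript_models(models)

  cds_share_ctrl <- 1 - utr5_occ_ctrl - cfg$utr3_occ
  cds_share_treat <- 1 - utr5_occ_treat - cfg$utr3_occ
  truth <- data.table(
    gene_id = gene_id, transcript_id = transcript_id, group = group,
    abundance = abundance, base_te = base_te,
    has_uorf = seq_len(n) %in% uorf_idx, kozak = kozak, uaug_pos = uaug_pos,
    true_rna_log2fc = true_rna_log2fc, true_te_log2fc = true_te_log2fc,
    utr5_occ_ctrl = utr5_occ_ctrl, utr5_occ_treat = utr5_occ_treat,
    utr3_occ = cfg$utr3_occ,
    expected_te_log2fc = true_te_log2fc +
      log2(cds_share_treat / cds_share_ctrl))
  list(models = models, truth = truth)
}

# Plant an AUG with the requested Kozak context into a 5'UTR sequence.
# Returns the modified sequence and the 0-based position of the A.
plant_uorf <- function(utr5, class) {
  L <- nchar(utr5)
  if (L < 13L) stop("5'UTR too short to host a uORF")  # config error upstream
  pos <- sample(3:(L - 10L), 1L)                        # 0-based A position
  ch <- strsplit(utr5, "")[[1L]]
  ch[(pos + 1L):(pos + 3L)] <- c("A", "T", "G")
  purine <- c("A", "G"); pyrim <- c("C", "T")
  if (class == "strong") {
    ch[pos - 2L] <- sample(purine, 1L); ch[pos + 4L] <- "G"
  } else if (class == "weak") {
    ch[pos - 2L] <- sample(pyrim, 1L)
    ch[pos + 4L] <- sample(c("A", "C", "T"), 1L)
  } else if (class == "adequate") {
    if (runif(1L) < 0.5) {
      ch[pos - 2L] <- sample(purine, 1L)
      ch[pos + 4L] <- sample(c("A", "C", "T"), 1L)
    } else {
      ch[pos - 2L] <- sample(pyrim, 1L); ch[pos + 4L] <- "G"
    }
  } else stop("unknown Kozak class: ", class)
  list(seq = paste(ch, collapse = ""), pos = pos)
}

# effect scale per condition: control 0, treatment 1, NAC arm partially
# reversed toward control
condition_scale <- function(condition, nac_reversal) {
  switch(condition, ctrl = 0, treat = 1, nac = 1 - nac_reversal,
         stop("unknown condition: ", condition))
}

#' Simulate RPF and RNA alignments
#'
#' Emits transcript-space alignments for every condition x replicate x
#' library in the config, plus the per-gene truth. Library totals are exact
#' (`reads_per_library`); per-gene counts are negative-binomially
#' overdispersed via a gamma rate multiplier before multinomial allocation.
#' RPF P-sites are placed by region (per-gene occupancies, shifted for
#' `uorf_shift` genes under treatment), with configured frame probabilities
#' within the CDS, then converted to read starts with the configured P-site
#' offset; RNA reads are uniform over the transcript.
#'
#' @param cfg a [sim_config()].
#' @param sim output of [simulate_transcriptome()] for the same config.
#' @return list: `alignments` (one `data.table`, all samples), `samples`
#'   (sample sheet: `sample_id`, `condition`, `replicate`), `truth`.
#' @export
simulate_reads <- function(cfg, sim) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  models <- sim$models; truth <- sim$truth
  n <- nrow(models)
  len <- models$length; cs <- models$cds_start; ce <- models$cds_end
  cds_len <- ce - cs
  L <- as.integer(cfg$reads_per_library)
  off <- cfg$psite_offset
  shape <- 1 / cfg$nb_dispersion

  sheet <- CJ(condition = cfg$conditions, replicate = seq_len(cfg$n_reps))
  sheet[, sample_id := paste0(condition, "_rep", replicate)]
  out <- vector("list", nrow(sheet) * 2L)
  ridx <- 0L
  for (s in seq_len(nrow(sheet))) {
    cond <- sheet$condition[s]
    sc <- condition_scale(cond, cfg$nac_reversal)
    rna_fold <- 2^(truth$true_rna_log2fc * sc)
    te_fold <- 2^(truth$true_te_log2fc * sc)
    p5 <- truth$utr5_occ_ctrl +
      sc * (truth$utr5_occ_treat - truth$utr5_occ_ctrl)
    p3 <- rep(cfg$utr3_occ, n)

    for (lib in c("rpf", "rna")) {
      w <- if (lib == "rna") truth$abundance * rna_fold * len
           else truth$abundance * rna_fold * truth$base_te * te_fold * cds_len
      g_noise <- rgamma(n, shape = shape, rate = shape)
      counts <- as.integer(rmultinom(1L, L, w * g_noise))
      gi <- rep.int(seq_len(n), counts)
      if (lib == "rna") {
        rl <- rep.int(cfg$rna_read_length, L)
        st <- as.integer(floor(runif(L) * (len[gi] - rl + 1L)))
      } else {
        rl <- sample(cfg$rpf_lengths, L, replace = TRUE,
                     prob = cfg$rpf_length_probs)
        u <- runif(L)
        reg <- fifelse(u < p5[gi], 1L, fifelse(u < p5[gi] + (1 - p5[gi] - p3[gi]), 2L, 3L))
        ps <- integer(L)
        i1 <- reg == 1L
        if (any(i1))
          ps[i1] <- off + as.integer(floor(runif(sum(i1)) * (cs[gi[i1]] - off)))
        i2 <- reg == 2L
        if (any(i2)) {
          ncod <- cds_len[gi[i2]] %/% 3L
          k <- as.integer(floor(runif(sum(i2)) * ncod))
          fu <- runif(sum(i2))
          fr <- fifelse(fu < cfg$frame_probs[1L], 0L,
                fifelse(fu < cfg$frame_probs[1L] + cfg$frame_probs[2L], 1L, 2L))
          ps[i2] <- cs[gi[i2]] + 3L * k + fr
        }
        i3 <- reg == 3L
        if (any(i3)) {
          lo <- ce[gi[i3]]
          hi <- len[gi[i3]] - rl[i3] + off          # last placeable P-site
          ps[i3] <- lo + as.integer(floor(runif(sum(i3)) * (hi - lo + 1L)))
        }
        st <- ps - off
      }
      ridx <- ridx + 1L
      out[[ridx]] <- data.table(
        transcript_id = models$transcript_id[gi],
        start = st, read_length = as.integer(rl),
        sample_id = sheet$sample_id[s], library = lib)
    }
  }
  aln <- rbindlist(out)
  list(alignments = validate_alignments(aln),
       samples = sheet[, .(sample_id, condition, replicate)],
       truth = truth)
}

#' Run a full simulation
#'
#' [simulate_transcriptome()] then [simulate_reads()] under one config.
#' @param cfg a [sim_config()].
#' @return list: `models`, `truth`, `alignments`, `samples`, `config`.
#' @export
simulate_study <- function(cfg) {
  sim <- simulate_transcriptome(cfg)
  rd <- simulate_reads(cfg, sim)
  list(models = sim$models, truth = rd$truth, alignments = rd$alignments,
       samples = rd$samples, config = cfg)
}

#' Write a simulated study to disk
#'
#' Emits FASTA (transcript sequences), transcript-space BED12, one TSV and
#' one SAM alignment file per sample x library, the truth table, the sample
#' sheet, a YAML echo of the config, and a manifest JSON with MD5 checksums
#' of every file. Byte-identical across runs with the same config.
#'
#' @param study output of [simulate_study()].
#' @param dir output directory (created).
#' @param sam also write SAM alongside TSV alignments (default TRUE).
#' @return invisibly, the manifest as a named list.
#' @export
write_simulation <- function(study, dir, sam = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  fa <- file.path(dir, "transcripts.fa")
  ss <- Biostrings::DNAStringSet(setNames(study$models$sequence,
                                          study$models$transcript_id))
  Biostrings::writeXStringSet(ss, fa)
  paths <- c(paths, fa)
  bed <- file.path(dir, "annotation.bed")
  write_annotation(study$models, bed)
  paths <- c(paths, bed)
  for (sid in study$samples$sample_id) {
    for (lib in c("rpf", "rna")) {
      sub <- study$alignments[sample_id == sid & library == lib]
      p <- file.path(dir, sprintf("%s_%s.tsv", sid, lib))
      write_alignments_tsv(sub, p)
      paths <- c(paths, p)
      if (sam) {
        p2 <- file.path(dir, sprintf("%s_%s.sam", sid, lib))
        write_alignments_sam(sub, study$models, p2)
        paths <- c(paths, p2)
      }
    }
  }
  tp <- file.path(dir, "truth.tsv")
  fwrite(study$truth, tp, sep = "\t")
  sp <- file.path(dir, "samples.tsv")
  fwrite(study$samples, sp, sep = "\t")
  cp <- file.path(dir, "config.yaml")
  yaml::write_yaml(unclass(study$config), cp)
  paths <- c(paths, tp, sp, cp)
  manifest <- list(files = as.list(setNames(unname(tools::md5sum(paths)),
                                            basename(paths))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
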