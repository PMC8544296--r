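---
title: "Quantifying translatome remodeling with riboshift: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying translatome remodeling with riboshift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riboshift)
library(data.table)
```

## The measurement model

Ribosome profiling sequences the ~30-nt mRNA fragments protected by
translating ribosomes (RPFs); paired RNA-seq measures mRNA abundance. From
reads aligned in transcript space, `riboshift` derives four families of
quantities:

* **Positional statistics.** Each RPF is reduced to its inferred ribosomal
  P-site, the read 5' end plus a fixed offset (default 12 nt, the standard
  value for ~30-nt mammalian footprints; overridable per read length). The
  P-site localises the ribosome to the 5'UTR `[0, cds_start)`, CDS
  `[cds_start, cds_end)` or 3'UTR `[cds_end, L)` of its transcript — all
  coordinates in this package are transcript-space, 0-based and half-open —
  and, within the CDS, to a reading frame `(psite - cds_start) mod 3`.
  Frame 0 is the annotated frame; a healthy library shows strong 3-nt
  periodicity (~75% frame 0) and CDS-concentrated occupancy (~90%).

* **Translation efficiency.** Per gene,
  `TE = RPKM_ribo(CDS) / FPKM_rna(transcript)`: ribosome footprint density on
  the coding region normalised by mRNA abundance. Only CDS-assigned RPFs
  count in the numerator; all reads on the transcript count in the
  denominator. TE is undefined (not zero) below an expression floor
  (default `rna_fpkm >= 1`), because the ratio is numerically unstable there.

* **The 5'UTR index.** Per transcript, the fraction of its RPF reads whose
  P-site falls in the 5'UTR. Only transcripts with at least one 5'UTR read
  enter the analysis. Under stress, genes regulated by upstream open reading
  frames (uORFs) move ribosome density out of the 5'UTR into the CDS
  (uORF bypass, the ATF4 paradigm); their 5'UTR index falls while their TE
  rises. The per-transcript `log2` change of the CDS:5'UTR RPF ratio
  (`shift_score()`, pseudocount 1) is the single-number detector of that
  signature.

* **uORF features.** `find_uorfs()` reports every AUG upstream of the
  annotated start, paired with the first in-frame stop scanning through the
  whole transcript (so uORFs may overlap the CDS; an AUG whose codon spans
  the 5'UTR/CDS boundary still counts). The initiation context is scored by
  the classical two-position Kozak rule — purine at -3 and G at +4 is
  `strong`, one of the two `adequate`, neither `weak` — rather than a PWM:
  the downstream reasoning is ordinal (stronger uAUG context and longer cap
  distance give stronger repression of the main ORF), and the two-position
  rule is exactly testable by enumeration. Near-cognate starts are excluded.

## Differential classification

Replicates are quantified independently; condition values are means across
replicates (the two-replicate design typical of these experiments precludes
heavier per-gene modeling by default; an optional two-sample t-test on log
values is attached for volcano-style output but never gates a call). A gene
is `up` at a level (rna / ribo / te) when
`log2((mean_treat + 0.5) / (mean_ctrl + 0.5)) >= 1`, `down` symmetrically,
otherwise `unchanged`; genes below the expression floor in both conditions
are `not_assessed`, never silently merged into `unchanged`. Whether a
"translational" change should be read off Ribo-seq RPKM or TE is ambiguous
in practice, so both levels are always computed and reported separately.

**Library-size normalisation.** RPKM with raw per-sample totals is
composition-sensitive: when a handful of strongly induced genes consume a
visibly larger share of one library, every unchanged gene's RPKM drifts the
other way, inflating false calls at a fixed fold-change threshold. We
therefore compute effective library sizes by DESeq-style median-of-ratios
within each library type (RNA on whole-transcript counts, RPF on CDS
counts), rescaled to the geometric mean of the raw totals so FPKM magnitudes
stay familiar. Under equal composition this reduces to the raw totals; raw
totals remain available (`normalize = "total"`). With very widespread
remodeling (e.g. half the translatome shifting) no normalisation can recover
absolute per-gene changes — a global component is unidentifiable — which is
why the group analyses below are relative (differences between gene groups),
and why we report medians over means where infinite ratios can occur.

## Group statistics

Following the figure-level analyses this package reproduces, the 5'UTR-index
*change* (treatment − control, per transcript; the per-condition index is
also emitted) is compared across TE classes by classical one-way ANOVA, and
the TE change between the `high_UTR` and `low_UTR` halves by the classical
equal-variance t-test (Welch available by flag). The high/low split is at
the median control 5'UTR index, implemented by rank so that group sizes
differ by at most one and records equal to the median go deterministically
to `low_UTR` (ties broken by transcript id). Degenerate inputs with zero
variance yield a flagged `NA` p-value, not an exception. Enrichment of gene
lists is a generic one-sided hypergeometric over-representation test against
user-supplied GMT collections with Benjamini–Hochberg adjustment; the
default universe is the genes with defined TE.

## What the simulator emulates

`sim_config()` defines a two-condition (optionally three: an antioxidant
arm that reverses 90% of every effect) study with two replicates and, by
default, 2 million reads per library. Its defaults are the study conditions
everything in this package is verified under:

| parameter | default | rationale |
|---|---|---|
| 5'UTR / CDS / 3'UTR lengths | lognormal, medians ~150 / 1200 / 400 nt (CDS a multiple of 3, AUG…stop) | typical mammalian mRNA architecture |
| abundance | lognormal, `sdlog = 1` | ~2 orders of magnitude of expression |
| baseline TE | lognormal, `sdlog = 1` | TE spans roughly 100-fold in mammalian cells |
| RPF occupancy (no uORF) | 5'UTR 6.5%, CDS 90.9%, 3'UTR 2.6% | the control-condition occupancy profile of a clean mammalian Ribo-seq library |
| frame probabilities | (0.749, 0.150, 0.101) | ~75% in-frame periodicity |
| RPF lengths | 26–34 nt, modal 30 | footprint length distribution |
| count noise | gamma–Poisson, dispersion 0.1 | negative-binomial replicate noise at bulk depth |
| uORF genes | 30% of genes; 5'UTR occupancy 0.25; Kozak-class TE multipliers 0.5 / 0.7 / 0.9 (strong / adequate / weak) | about half of human transcripts carry uORFs; stronger context, stronger repression |
| `uorf_shift` genes | 5'UTR occupancy 0.40 → 0.10 under treatment | the uORF-bypass signature |
| effect sizes | \|log2FC\| = 2 at the RNA or ribosome-loading level | recoverable at desk scale with 2 replicates |

Counts are drawn by multiplying each gene's expected share (abundance ×
length for RNA; abundance × TE × CDS length for RPF) by a per-gene gamma
variate and allocating the configured library total multinomially — the
library size is exact and the per-gene counts are negative-binomially
overdispersed. P-sites are placed uniformly within the sampled region (with
the configured frame probabilities inside the CDS) and converted to read
starts with the placement offset, so quantification with the same offset
recovers the generating occupancies exactly up to multinomial noise. The
expected-truth table records, per gene, the intrinsic fold changes *and* the
extra CDS-share fold that an occupancy shift mechanically induces in
CDS-restricted TE (`expected_te_log2fc`), which is what the estimator should
see.

One deliberate idealisation matters for interpreting the recovery tests:
effects are applied to per-gene rates with everything else held fixed, reads
are emitted directly as transcript-space alignments (no sequencing errors,
no mappability artefacts, no multi-mapping — alignment is upstream of this
package's scope), and occupancies are homogeneous within a gene class.
Passing parameter recovery here demonstrates the estimators are correct and
calibrated under the declared noise model; it does not certify behaviour
under alignment bias, UTR mis-annotation, or dispersion far from 0.1.

## Numerical and procedural choices

* Transcript coordinates: 0-based half-open everywhere; BED12 is native
  input (1-based GTF converted on read); the stop codon is inside
  `[cds_start, cds_end)`, matching BED thick-interval practice, so frame
  arithmetic is unambiguous.
* Multi-isoform genes: analysis is per-transcript; gene-level values use one
  canonical transcript per gene (longest CDS by default, configurable).
* Pseudocounts: 0.5 on condition-mean FPKM before fold changes; 1 on both
  terms of the CDS:5'UTR ratio (keeps every shift score finite).
* Reads shorter than 20 nt are excluded before any counting.
* P-sites falling outside their transcript are flagged and excluded from
  positional statistics rather than clipped.
* uORFs with no in-frame stop anywhere in the transcript carry a sentinel
  (`stop_pos = NA`), count as CDS-overlapping, and are excluded from length
  statistics.
* Empty results (no usable reads, no CDS P-sites) are explicit zero-row
  tables, never NaN percentages.
* All randomness flows from a single integer seed per simulation config;
  the same config is bit-for-bit reproducible, including on-disk output
  (checksummed in a manifest).

## Problem sizes used in verification

The packaged checks run three study designs chosen to exercise every
estimator at bulk-study depth while staying desk-sized: a 1,000-gene mixed
study at 2 million reads per library (TE recovery, classification
sensitivity/specificity, occupancy and frame recovery), a 1,000-gene
uORF-shift study at ~200 RPFs per transcript (5'UTR-index directionality,
high/low-UTR group statistics, shift-score ranking), and small studies
(30–60 genes) for exact properties such as determinism and round-trips.
Statistical calibration uses 1,000 null replications for test uniformity and
500 null queries for FDR control. The numbered scripts under `analysis/`
run the same chain at 2–5 × 10^5 reads per library so their written outputs
stay small; depth only tightens the Monte-Carlo error of what they print.

## Known limitations

* The composition caveat above: absolute fold changes are unidentifiable
  when a large fraction of the translatome moves in one direction; only
  spike-ins could anchor them.
* With two replicates the classifier is a thresholded fold change, not a
  significance test; the attached t-test is descriptive.
* Kozak scoring ignores positions other than -3/+4 and secondary structure;
  cap distance is a proxy for scanning-time effects, not a kinetic model.
* RNA reads are counted once per transcript of the provided alignments; no
  multi-mapping resolution is attempted.
* The enrichment engine ships no gene-set databases; term lists are the
  user's responsibility.
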