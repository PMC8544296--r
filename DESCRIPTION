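Package: riboshift
Title: Translatome Remodeling Analysis from Ribosome Profiling and RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies translational control from paired ribosome profiling
    (Ribo-seq) and RNA-seq libraries aligned in transcript space. Computes
    P-site based region and reading-frame occupancy, CDS-restricted RPKM and
    translation efficiency (TE), differential classification at the
    transcriptional and translational levels, the 5'UTR ribosome occupancy
    index with high/low-UTR group statistics, upstream open reading frame
    (uORF) detection with Kozak-context scoring, CDS:5'UTR ribosome density
    shift scores for uORF-bypass induction, and generic hypergeometric
    over-representation analysis. Ships a seeded synthetic-data generator
    (transcriptome, uORFs, negative-binomial RNA/RPF alignments with known
    per-gene truth) so every stage is verifiable by parameter recovery
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table (>= 1.14),
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    BiocGenerics,
    S4Vectors,
    IRanges,
    Biostrings,
    rtracklayer,
    Rsamtools,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
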