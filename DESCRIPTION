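Package: initscan
Title: Promoter-Scanning Analysis of Transcription Start Site Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Genome-wide analysis of transcription start site (TSS)
    selection under the RNA polymerase II promoter-scanning ("shooting
    gallery") model in budding yeast. Computes per-promoter TSS
    distribution metrics (median TSS, TSS spread, expression, normalized
    densities), directional TSS usage and efficiency statistics, 64-way
    N-8/N-1/N+1 initiation-motif decompositions, core-promoter element
    scans (TATA consensus, TATA-like, GA-rich elements), strand-specific
    ChIP-exo median positioning of pre-initiation-complex components,
    and MNase-seq nucleosome midpoint smoothing, peak calling, +1
    nucleosome assignment and nucleosome repeat length estimation by
    autocorrelation. Includes a seeded scanning-model simulator that
    generates synthetic genomes, promoters, TSS-seq, ChIP-exo and MNase
    data so polar-shift and nucleosome-spacing findings can be
    reproduced as parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    Rsamtools,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
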