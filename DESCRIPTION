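Package: nucMACCr
Title: Nucleosome Accessibility and Stability Scoring from MNase Titration Data
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Calls nucleosome and sub-nucleosome positions from size-classified
    MNase-seq fragments sequenced over a titration of MNase concentrations, and
    scores each position for linker accessibility (nucMACC) and particle
    stability (sub-nucMACC) by regressing log2 normalized fragment counts on
    log2 MNase concentration, with LOESS-based GC-bias correction.
    Hyper-/hypo-accessible and unstable/noncanonical nucleosomes are selected
    by a rank-slope cutoff on the normalized score curve. Includes a seeded
    simulator of MNase titration experiments with known per-nucleosome
    accessibility and stability for end-to-end validation, fragments-per-
    nucleosome (FPN) sequencing-depth diagnostics, and spike-in normalization.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    data.table,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomeInfoDb,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    Rsamtools,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
biocViews: Epigenetics, NucleosomePositioning, Sequencing, Coverage
RoxygenNote: 7.3.3
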