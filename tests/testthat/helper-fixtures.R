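## Shared fixtures, built in code at test time.

quietly <- function(expr) suppressMessages(suppressWarnings(expr))

testGenome <- function(sizes = c(chrT = 10000), fasta = NULL) {
    GenomeInfo(sizes, fastaPath = fasta %||% NA_character_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

testSample <- function(id = "s1", conc = 1.5, rep = "rep1", spike = NA) {
    SampleMeta(id, conc, rep, spike)
}

# FragmentSet from 0-based half-open coordinates
makeFragments <- function(starts0, ends0, chrom = "chrT",
                          genome = testGenome(), sample = testSample(),
                          fraction = "all") {
    gr <- GenomicRanges::GRanges(
        rep(chrom, length(starts0)),
        IRanges::IRanges(start = starts0 + 1L, end = ends0),
        seqinfo = GenomeInfoDb::Seqinfo(names(chromSizes(genome)),
                                        as.integer(chromSizes(genome))))
    FragmentSet(gr, sample, fraction)
}

# PositionSet from 1-based starts with fixed width; summit at center
makePositions <- function(starts1, width = 147, chrom = "chrT",
                          kind = "mono", occupancy = 1) {
    gr <- GenomicRanges::GRanges(
        chrom, IRanges::IRanges(start = starts1, width = width))
    S4Vectors::mcols(gr)$summit <- as.integer(starts1 + width %/% 2L)
    S4Vectors::mcols(gr)$occupancy <- rep_len(occupancy, length(starts1))
    PositionSet(gr, kind)
}

# write a FASTA and return a GenomeInfo pointing at it
writeTestFasta <- function(seqs, dir = withr::local_tempdir(.local_envir =
                                                            parent.frame())) {
    path <- file.path(dir, "test_genome.fa")
    dss <- Biostrings::DNAStringSet(unlist(seqs))
    names(dss) <- names(seqs)
    Biostrings::writeXStringSet(dss, path)
    GenomeInfo(vapply(seqs, nchar, numeric(1)), fastaPath = path)
}

# tiny paired-end BAM built from SAM text; returns the BAM path
writeTestBam <- function(samLines, dir = withr::local_tempdir(.local_envir =
                                                              parent.frame())) {
    samPath <- file.path(dir, "toy.sam")
    writeLines(samLines, samPath)
    Rsamtools::asBam(samPath, file.path(dir, "toy"), overwrite = TRUE,
                     indexDestination = TRUE)
}

samPair <- function(qname, chrom, leftPos, rightPos, tlen, mapq,
                    readLen = 50) {
    seq <- strrep("A", readLen)
    c(paste(qname, 99, chrom, leftPos, mapq, paste0(readLen, "M"), "=",
            rightPos, tlen, seq, "*", sep = "\t"),
      paste(qname, 147, chrom, rightPos, mapq, paste0(readLen, "M"), "=",
            leftPos, -tlen, seq, "*", sep = "\t"))
}

samHeader <- function(chrom = "chrT", len = 10000) {
    c("@HD\tVN:1.6\tSO:unsorted",
      paste0("@SQ\tSN:", chrom, "\tLN:", len))
}

# NucCountMatrix with literal counts (positions spaced 300 bp apart)
toyCountMatrix <- function(counts, conc, kind = "mono",
                           libSize = rep(1e6, length(conc)),
                           spike = rep(NA_real_, length(conc)),
                           repl = paste0("rep", seq_along(conc))) {
    counts <- as.matrix(counts)
    n <- nrow(counts)
    ps <- makePositions(seq(1, by = 300, length.out = n), kind = kind)
    gr <- positions(ps)
    S4Vectors::mcols(gr)$totalCount <- rowSums(counts)
    colnames(counts) <- paste0("s", seq_along(conc))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts), rowRanges = gr,
        colData = S4Vectors::DataFrame(
            sampleId = paste0("s", seq_along(conc)),
            concentration = conc, replicateLabel = repl,
            spikeInFragments = spike, libSize = libSize))
    methods::new("NucCountMatrix", se, kind = kind, normState = "raw",
                 pseudocount = NA_real_)
}

# memoized heavyweight simulations shared across acceptance tests
.simCache <- new.env(parent = emptyenv())

cachedRecoveryRun <- function() {
    if (is.null(.simCache$rec)) {
        cfg <- SimConfig(nNucleosomes = 1000, seed = 7)
        dir <- file.path(tempdir(), "acc_recovery")
        sim <- quietly(simulateTwoVsFour(cfg, dir))
        res4 <- quietly(runNucMACC(sim$sheetPath, sim$genome))
        .simCache$rec <- list(cfg = cfg, sim = sim, res4 = res4)
    }
    .simCache$rec
}
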