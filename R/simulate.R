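## Seeded simulator of MNase titration experiments with known ground truth.

#' Simulate an MNase titration experiment
#'
#' Generates a titration experiment with known per-nucleosome accessibility
#' and stability, as plain-text files (per-sample fragment BED3, genome
#' FASTA, sample sheet TSV, truth TSV) under one directory.
#'
#' The generative model makes the planted parameters the estimand of the
#' scoring regression. Nucleosomes are placed at uniformly spaced dyads; for
#' a sample at concentration \code{c}, mono-nucleosomal fragment counts at
#' nucleosome i are Poisson with mean \code{depth * c^(-a_i)}, so the
#' expected log2 count falls on a line in log2 c with slope \code{-a_i} and
#' the recovered nucMACC score estimates \code{a_i} (positive = released
#' preferentially at mild digestion). Sub-nucleosomal counts are Poisson with
#' mean \code{depth * w_i * c^(s_i)}: the planted stability \code{s_i} is the
#' expected sub-nucMACC slope, and the sub emission weight \code{w_i} equals
#' \code{subFractionWeight} for a planted fragile subpopulation
#' (\code{fragileFraction} of nucleosomes) and \code{baselineSubWeight}
#' elsewhere, which is what makes fragile positions survive the
#' unique-or-fourfold informativeness filter. Fragment lengths are normal
#' (mono clipped to [140, 200), sub to (0, 140)) and midpoints are jittered
#' around the dyad. The genome sequence is drawn with per-nucleosome target
#' GC; with \code{gcBiasBeta != 0} counts acquire a concentration-coupled GC
#' bias \code{2^(gcBiasBeta * (g_i - gcMean) * log2 c)}, which perturbs the
#' apparent release exponent by \code{-gcBiasBeta * (g_i - gcMean)} -- the
#' bias the LOESS GC correction is designed to remove.
#'
#' A fixed seed yields byte-identical output files.
#'
#' @param cfg a \code{\link{SimConfig}}.
#' @param dir output directory (created if needed).
#' @return list with \code{sheetPath}, \code{sheet} (data.frame),
#'   \code{genome} (a \code{\link{GenomeInfo}} pointing at the written
#'   FASTA), \code{truth} (data.frame: chrom, dyad (1-based), accessibility,
#'   stability, fragile, gc), \code{truthPath} and \code{dir}.
#' @export
simulateExperiment <- function(cfg, dir = tempfile("mnase_sim_")) {
    stopifnot(is(cfg, "SimConfig"))
    validObject(cfg)
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    set.seed(cfg@seed)
    margin <- 400L
    nucWidth <- 147L

    n <- cfg@nNucleosomes
    perChrom <- diff(round(seq(0, n, length.out = cfg@nChromosomes + 1L)))
    chromNames <- sprintf("chrSim%d", seq_len(cfg@nChromosomes))
    dyads <- integer(0); chromOf <- character(0); chromLen <- integer(0)
    for (k in seq_len(cfg@nChromosomes)) {
        nk <- perChrom[k]
        sp <- round(stats::runif(nk, cfg@spacing[1L], cfg@spacing[2L]))
        d <- margin + cumsum(sp)
        dyads <- c(dyads, d)
        chromOf <- c(chromOf, rep(chromNames[k], nk))
        chromLen <- c(chromLen, max(d) + margin)
    }
    names(chromLen) <- chromNames

    a <- cfg@accessibilityDist(n)
    s <- cfg@stabilityDist(n)
    fragile <- stats::runif(n) < cfg@fragileFraction
    w <- ifelse(fragile, cfg@subFractionWeight, cfg@baselineSubWeight)
    g <- pmin(0.8, pmax(0.2, stats::rnorm(n, cfg@gcMean, cfg@gcSd)))

    ## genome sequence with per-nucleosome target GC over the core interval
    half <- (nucWidth - 1L) %/% 2L
    seqs <- character(cfg@nChromosomes)
    for (k in seq_len(cfg@nChromosomes)) {
        L <- chromLen[k]
        prob <- rep(0.40, L)
        inChrom <- chromOf == chromNames[k]
        idx <- rep(dyads[inChrom] - half, each = nucWidth) +
            rep(0:(nucWidth - 1L), sum(inChrom))
        prob[idx] <- rep(g[inChrom], each = nucWidth)
        isGC <- stats::runif(L) < prob
        pick <- stats::runif(L) < 0.5
        base <- ifelse(isGC, ifelse(pick, "G", "C"), ifelse(pick, "A", "T"))
        seqs[k] <- paste(base, collapse = "")
    }
    fastaPath <- file.path(dir, "genome.fa")
    dss <- Biostrings::DNAStringSet(seqs)
    names(dss) <- chromNames
    Biostrings::writeXStringSet(dss, fastaPath)
    genome <- GenomeInfo(chromLen, fastaPath = fastaPath)

    ## per-sample fragments
    conc <- rep(cfg@concentrations, each = cfg@replicates)
    repl <- rep(seq_len(cfg@replicates), length(cfg@concentrations))
    concLab <- vapply(conc, function(x) format(x, trim = TRUE,
                                               scientific = FALSE),
                      character(1))
    sampleIds <- sprintf("c%s_rep%d", concLab, repl)
    spike <- if (all(is.na(cfg@spikeIn))) rep(NA_real_, length(conc))
             else rep_len(cfg@spikeIn, length(conc))
    bedNames <- paste0(sampleIds, ".bed")
    for (j in seq_along(conc)) {
        cj <- conc[j]
        bias <- if (cfg@gcBiasBeta != 0)
            2^(cfg@gcBiasBeta * (g - cfg@gcMean) * log2(cj)) else 1
        lamM <- cfg@depth * cj^(-a) * bias
        lamS <- cfg@depth * w * cj^(s) * bias
        nM <- stats::rpois(n, lamM)
        nS <- stats::rpois(n, lamS)
        lenM <- pmin(199L, pmax(140L, round(stats::rnorm(
            sum(nM), cfg@monoLength[1L], cfg@monoLength[2L]))))
        lenS <- pmin(139L, pmax(1L, round(stats::rnorm(
            sum(nS), cfg@subLength[1L], cfg@subLength[2L]))))
        dy <- c(rep(dyads, nM), rep(dyads, nS))
        chr <- c(rep(chromOf, nM), rep(chromOf, nS))
        len <- c(lenM, lenS)
        mid <- dy + round(stats::rnorm(length(dy), 0, cfg@jitterSd))
        start0 <- mid - len %/% 2L
        end0 <- start0 + len
        maxLen <- chromLen[chr]
        start0 <- pmax(0L, pmin(start0, maxLen - 1L))
        end0 <- pmax(start0 + 1L, pmin(end0, maxLen))
        df <- data.frame(chrom = chr, start = start0, end = end0)
        df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
        data.table::fwrite(df, file.path(dir, bedNames[j]), sep = "\t",
                           col.names = FALSE)
    }

    sheet <- data.frame(sample_id = sampleIds, path = bedNames,
                        concentration_U = conc, replicate =
                            sprintf("rep%d", repl),
                        spike_in_fragments = spike)
    sheetPath <- file.path(dir, "samples.tsv")
    data.table::fwrite(sheet, sheetPath, sep = "\t", col.names = TRUE)

    truth <- data.frame(chrom = chromOf, dyad = dyads, accessibility = a,
                        stability = s, fragile = fragile, gc = g)
    truthPath <- file.path(dir, "truth.tsv")
    data.table::fwrite(truth, truthPath, sep = "\t", col.names = TRUE)
    data.table::fwrite(data.frame(chrom = chromNames,
                                  size = as.integer(chromLen)),
                       file.path(dir, "chrom.sizes"), sep = "\t",
                       col.names = FALSE)

    sheet$path <- file.path(dir, sheet$path)
    list(sheetPath = sheetPath, sheet = sheet, genome = genome,
         truth = truth, truthPath = truthPath, dir = dir)
}

#' Simulate paired two- versus four-titration designs
#'
#' Runs \code{\link{simulateExperiment}} once over all concentrations and
#' additionally emits a sample sheet restricted to the lowest and highest
#' concentration, so the same planted truth can be scored under both designs
#' (the four-condition design strictly contains the two-condition samples).
#' Warns when the concentration span is under 10-fold, the recommended
#' minimum gap between the two titration points.
#'
#' @param cfg a \code{\link{SimConfig}} with >= 2 concentrations.
#' @param dir output directory.
#' @return the \code{simulateExperiment} result, plus \code{twoSheet}
#'   (data.frame) and \code{twoSheetPath}.
#' @export
simulateTwoVsFour <- function(cfg, dir = tempfile("mnase_sim_")) {
    sim <- simulateExperiment(cfg, dir)
    conc <- cfg@concentrations
    if (max(conc) / min(conc) < 10)
        warning("concentration span under 10-fold; two-titration scores may ",
                "be unreliable")
    keep <- sim$sheet$concentration_U %in% range(conc)
    two <- sim$sheet[keep, , drop = FALSE]
    twoPath <- file.path(dir, "samples_two.tsv")
    out <- two
    out$path <- basename(out$path)
    data.table::fwrite(out, twoPath, sep = "\t", col.names = TRUE)
    c(sim, list(twoSheet = two, twoSheetPath = twoPath))
}

#' Match called positions to planted nucleosomes
#'
#' Joins positions to the truth table by nearest dyad: a position matches the
#' planted nucleosome whose dyad is closest to its summit, within
#' \code{maxDist} bp on the same chromosome.
#'
#' @param x a \code{\link{PositionSet}} or \code{\link{ScoreTable}}.
#' @param truth the truth data.frame from \code{\link{simulateExperiment}}.
#' @param maxDist maximum summit-dyad distance (bp, default 73).
#' @return integer vector of truth row indices (NA where unmatched), one per
#'   position.
#' @export
matchPositionsToTruth <- function(x, truth, maxDist = 73) {
    gr <- positions(x)
    summit <- S4Vectors::mcols(gr)$summit
    posGr <- GRanges(GenomicRanges::seqnames(gr),
                     IRanges(start = summit, width = 1L))
    truthGr <- GRanges(truth$chrom, IRanges(start = truth$dyad, width = 1L))
    out <- rep(NA_integer_, length(gr))
    if (length(truthGr) == 0L || length(posGr) == 0L) return(out)
    near <- GenomicRanges::distanceToNearest(posGr, truthGr,
                                             ignore.strand = TRUE)
    ok <- S4Vectors::mcols(near)$distance <= maxDist
    out[S4Vectors::queryHits(near)[ok]] <- S4Vectors::subjectHits(near)[ok]
    out
}
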