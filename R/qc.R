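## Sequencing-depth and replicate-consistency diagnostics.

#' Fragments per nucleosome (FPN)
#'
#' FPN normalizes sequencing depth to the expected number of nucleosomes in
#' the genome: \code{FPN = n / (G / L)}, with \code{G} the effective genome
#' size and \code{L} the nucleosome repeat length (170 bp is a reasonable
#' genome-wide approximation).
#'
#' @param nFragments number of sequenced fragments.
#' @param genome a \code{\link{GenomeInfo}}.
#' @param repeatLength nucleosome repeat length in bp (default 170).
#' @return the FPN value (dimensionless).
#' @export
computeFPN <- function(nFragments, genome, repeatLength = 170) {
    if (repeatLength <= 0) stop("repeatLength must be positive")
    G <- effectiveGenomeSize(genome)
    if (G <= 0) stop("effective genome size must be positive")
    nFragments / (G / repeatLength)
}

#' FPN depth report
#'
#' Bundles the three depth metrics of a titration experiment:
#' \code{fpnTotal} from all sequenced fragments of all samples,
#' \code{fpnMono} from the size-selected mono fragments of all samples, and
#' \code{fpnSub} from the sub fragments of the lowest-concentration
#' sample(s) only (the only ones used for sub-nucleosome position calling).
#' Warns when \code{fpnTotal} falls below 240, the recommended minimum depth
#' for a meaningful sub-nucleosome (stability) analysis.
#'
#' @param nTotal,nMono,nSubLowest fragment counts (see above).
#' @param genome a \code{\link{GenomeInfo}}.
#' @param repeatLength nucleosome repeat length (bp).
#' @return list with \code{fpnTotal}, \code{fpnMono}, \code{fpnSub},
#'   \code{nNucleosomesExpected}, \code{repeatLength},
#'   \code{effectiveGenomeSize}.
#' @export
fpnReport <- function(nTotal, nMono, nSubLowest, genome, repeatLength = 170) {
    rep <- list(fpnTotal = computeFPN(nTotal, genome, repeatLength),
                fpnMono = computeFPN(nMono, genome, repeatLength),
                fpnSub = computeFPN(nSubLowest, genome, repeatLength),
                nNucleosomesExpected =
                    effectiveGenomeSize(genome) / repeatLength,
                repeatLength = repeatLength,
                effectiveGenomeSize = effectiveGenomeSize(genome))
    if (rep$fpnTotal < 240)
        warning(sprintf(paste0("FPN(total) = %.1f is below 240; sub-",
                               "nucleosome (stability) analysis is likely ",
                               "underpowered"), rep$fpnTotal))
    rep
}

#' Fragment-size histogram
#'
#' Normalized length-frequency table of a fragment set, annotated with the
#' mono/sub size boundaries.
#'
#' @param fs a \code{FragmentSet}.
#' @param bin bin width in bp (default 1).
#' @return data.frame with \code{length} (bin start), \code{count} and
#'   \code{frequency} (summing to 1); attributes \code{monoMin} (140) and
#'   \code{monoMax} (200) mark the size-class boundaries.
#' @export
fragmentSizeHistogram <- function(fs, bin = 1) {
    stopifnot(is(fs, "FragmentSet"))
    w <- GenomicRanges::width(fragments(fs))
    if (length(w) == 0L) {
        warning("empty fragment set; empty histogram")
        out <- data.frame(length = numeric(0), count = integer(0),
                          frequency = numeric(0))
    } else {
        b <- (w %/% bin) * bin
        tab <- table(b)
        out <- data.frame(length = as.numeric(names(tab)),
                          count = as.integer(tab),
                          frequency = as.integer(tab) / length(w))
    }
    attr(out, "monoMin") <- 140
    attr(out, "monoMax") <- 200
    out
}

#' Replicate-consistency correlations
#'
#' Pearson correlation of \code{log2(normalized count + pseudocount)} between
#' replicate samples at the same MNase concentration.
#'
#' @param cm a normalized \code{\link{NucCountMatrix}} (>= 50 positions).
#' @param pseudocount optional fixed pseudocount; computed from \code{cm}
#'   when \code{NULL}.
#' @return data.frame with one row per replicate pair: \code{concentration},
#'   \code{sample1}, \code{sample2}, \code{r}.
#' @export
replicateCorrelation <- function(cm, pseudocount = NULL) {
    stopifnot(is(cm, "NucCountMatrix"))
    if (normState(cm) == "raw")
        stop("replicateCorrelation expects normalized counts")
    if (nrow(cm) < 50L)
        warning("fewer than 50 shared positions; correlations unstable")
    p <- pseudocount %||% computePseudocount(cm)
    a <- log2(SummarizedExperiment::assay(cm, "counts") + p)
    cd <- SummarizedExperiment::colData(cm)
    out <- data.frame(concentration = numeric(0), sample1 = character(0),
                      sample2 = character(0), r = numeric(0))
    for (conc in unique(cd$concentration)) {
        idx <- which(cd$concentration == conc)
        if (length(idx) < 2L) {
            warning("no replicate pairing at ", conc, " U; skipped")
            next
        }
        for (i in seq_along(idx)[-length(idx)]) {
            for (j in (i + 1L):length(idx)) {
                out <- rbind(out, data.frame(
                    concentration = conc,
                    sample1 = cd$sampleId[idx[i]],
                    sample2 = cd$sampleId[idx[j]],
                    r = stats::cor(a[, idx[i]], a[, idx[j]])))
            }
        }
    }
    out
}
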