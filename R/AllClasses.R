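#' @import methods
#' @importFrom GenomicRanges GRanges seqnames start end width strand findOverlaps
#'   countOverlaps pintersect coverage trim sort
#' @importFrom IRanges IRanges subsetByOverlaps overlapsAny
#' @importFrom S4Vectors mcols mcols<- metadata metadata<- queryHits subjectHits
#'   DataFrame
#' @importFrom BiocGenerics cbind rbind
#' @importFrom stats median quantile rnorm runif rpois cor loess fitted
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<- colData
#'   rowRanges
NULL

## ---------------------------------------------------------------------------
## GenomeInfo
## ---------------------------------------------------------------------------

#' Genome bookkeeping for an MNase titration analysis
#'
#' Holds chromosome sizes, the effective (mappable) genome size used for
#' coverage normalization, and an optional path to an indexed FASTA used to
#' measure GC content at called positions.
#'
#' @slot chromSizes named numeric vector of chromosome lengths (bp).
#' @slot effectiveGenomeSize numeric scalar, mappable genome size in bp.
#' @slot fastaPath character scalar, path to the genome FASTA or \code{NA}.
#'
#' @export
setClass("GenomeInfo",
    representation(chromSizes = "numeric",
                   effectiveGenomeSize = "numeric",
                   fastaPath = "character"))

setValidity("GenomeInfo", function(object) {
    msg <- NULL
    cs <- object@chromSizes
    if (length(cs) == 0L || is.null(names(cs)) || any(!nzchar(names(cs))))
        msg <- c(msg, "chromSizes must be a non-empty named vector")
    if (any(cs <= 0))
        msg <- c(msg, "all chromosome sizes must be > 0")
    if (length(object@effectiveGenomeSize) != 1L ||
        object@effectiveGenomeSize <= 0)
        msg <- c(msg, "effectiveGenomeSize must be a positive scalar")
    if (length(cs) && object@effectiveGenomeSize > sum(cs))
        msg <- c(msg, "effectiveGenomeSize cannot exceed the summed chromosome sizes")
    if (length(object@fastaPath) != 1L)
        msg <- c(msg, "fastaPath must be a single path or NA")
    if (is.null(msg)) TRUE else msg
})

#' @param chromSizes named numeric vector of chromosome lengths (bp).
#' @param effectiveGenomeSize mappable genome size in bp; defaults to the sum
#'   of \code{chromSizes}.
#' @param fastaPath optional path to the genome FASTA (indexed on demand).
#' @return A \code{GenomeInfo} object.
#' @rdname GenomeInfo-class
#' @export
GenomeInfo <- function(chromSizes, effectiveGenomeSize = sum(chromSizes),
                       fastaPath = NA_character_) {
    new("GenomeInfo", chromSizes = chromSizes,
        effectiveGenomeSize = as.numeric(effectiveGenomeSize),
        fastaPath = as.character(fastaPath))
}

## ---------------------------------------------------------------------------
## SampleMeta
## ---------------------------------------------------------------------------

#' Metadata for one MNase titration sample
#'
#' @slot sampleId unique sample identifier.
#' @slot concentration MNase concentration in units (U); must be positive.
#' @slot replicateLabel replicate label (e.g. "rep1").
#' @slot spikeInFragments number of spike-in derived fragments, or \code{NA}.
#'
#' @export
setClass("SampleMeta",
    representation(sampleId = "character",
                   concentration = "numeric",
                   replicateLabel = "character",
                   spikeInFragments = "numeric"))

setValidity("SampleMeta", function(object) {
    msg <- NULL
    if (length(object@sampleId) != 1L || !nzchar(object@sampleId))
        msg <- c(msg, "sampleId must be a non-empty string")
    if (length(object@concentration) != 1L || is.na(object@concentration) ||
        object@concentration <= 0)
        msg <- c(msg, "concentration must be a positive scalar (MNase units)")
    if (!is.na(object@spikeInFragments) && object@spikeInFragments < 0)
        msg <- c(msg, "spikeInFragments must be nonnegative")
    if (is.null(msg)) TRUE else msg
})

#' @param sampleId unique sample identifier.
#' @param concentration MNase concentration (U).
#' @param replicateLabel replicate label.
#' @param spikeInFragments spike-in fragment count or \code{NA}.
#' @return A \code{SampleMeta} object.
#' @rdname SampleMeta-class
#' @export
SampleMeta <- function(sampleId, concentration, replicateLabel = "rep1",
                       spikeInFragments = NA_real_) {
    new("SampleMeta", sampleId = as.character(sampleId),
        concentration = as.numeric(concentration),
        replicateLabel = as.character(replicateLabel),
        spikeInFragments = as.numeric(spikeInFragments))
}

## ---------------------------------------------------------------------------
## FragmentSet
## ---------------------------------------------------------------------------

.FRACTIONS <- c("all", "mono", "sub")

#' Sequenced fragments for one sample and size fraction
#'
#' Paired-end template spans for one sample, stored as a \code{GRanges}.
#' The \code{fraction} records whether the set is unselected (\code{"all"}),
#' mono-nucleosomal or sub-nucleosomal; \code{sizeRange} records the length
#' window enforced by \code{\link{classifyBySize}} (half-open \code{[lo, hi)}),
#' \code{NA} for unselected sets.
#'
#' @slot fragments \code{GRanges} of fragment intervals.
#' @slot sample \code{SampleMeta} for the originating sample.
#' @slot fraction one of \code{"all"}, \code{"mono"}, \code{"sub"}.
#' @slot sizeRange numeric length-2, enforced half-open length window or NAs.
#'
#' @export
setClass("FragmentSet",
    representation(fragments = "GRanges",
                   sample = "SampleMeta",
                   fraction = "character",
                   sizeRange = "numeric"))

setValidity("FragmentSet", function(object) {
    msg <- NULL
    if (!object@fraction %in% .FRACTIONS)
        msg <- c(msg, "fraction must be one of 'all', 'mono', 'sub'")
    if (length(object@sizeRange) != 2L)
        msg <- c(msg, "sizeRange must have length 2")
    w <- GenomicRanges::width(object@fragments)
    sr <- object@sizeRange
    if (length(w)) {
        if (!is.na(sr[1L]) && any(w < sr[1L]))
            msg <- c(msg, "fragment lengths below the enforced sizeRange")
        if (!is.na(sr[2L]) && any(w >= sr[2L]))
            msg <- c(msg, "fragment lengths at/above the enforced sizeRange")
    }
    if (is.null(msg)) TRUE else msg
})

#' @param fragments \code{GRanges} of fragment intervals.
#' @param sample a \code{SampleMeta}.
#' @param fraction size fraction label.
#' @param sizeRange enforced half-open length window, or \code{c(NA, NA)}.
#' @return A \code{FragmentSet}.
#' @rdname FragmentSet-class
#' @export
FragmentSet <- function(fragments, sample, fraction = "all",
                        sizeRange = c(NA_real_, NA_real_)) {
    new("FragmentSet", fragments = fragments, sample = sample,
        fraction = fraction, sizeRange = as.numeric(sizeRange))
}

## ---------------------------------------------------------------------------
## PositionSet
## ---------------------------------------------------------------------------

#' Called (sub-)nucleosome positions
#'
#' Positions are fixed-width intervals centered on pileup summits. The
#' underlying \code{GRanges} carries metadata columns \code{summit} (1-based
#' genomic coordinate of the pileup maximum) and \code{occupancy} (normalized
#' smoothed pileup height at the summit).
#'
#' @slot positions \code{GRanges} with \code{summit} and \code{occupancy}.
#' @slot kind \code{"mono"} or \code{"sub"}.
#'
#' @export
setClass("PositionSet",
    representation(positions = "GRanges", kind = "character"))

setValidity("PositionSet", function(object) {
    msg <- NULL
    if (!object@kind %in% c("mono", "sub"))
        msg <- c(msg, "kind must be 'mono' or 'sub'")
    mc <- S4Vectors::mcols(object@positions)
    if (!all(c("summit", "occupancy") %in% colnames(mc)))
        msg <- c(msg, "positions must carry 'summit' and 'occupancy' columns")
    else {
        s <- mc$summit
        if (length(s) && (any(s < GenomicRanges::start(object@positions)) ||
                          any(s > GenomicRanges::end(object@positions))))
            msg <- c(msg, "summits must lie within their position intervals")
    }
    if (is.null(msg)) TRUE else msg
})

#' @param positions \code{GRanges} with \code{summit} and \code{occupancy}
#'   metadata columns.
#' @param kind \code{"mono"} or \code{"sub"}.
#' @return A \code{PositionSet}.
#' @rdname PositionSet-class
#' @export
PositionSet <- function(positions, kind) {
    new("PositionSet", positions = positions, kind = kind)
}

## ---------------------------------------------------------------------------
## NucCountMatrix
## ---------------------------------------------------------------------------

#' Positions-by-samples fragment count matrix
#'
#' Extends \code{RangedSummarizedExperiment}: rows are called positions
#' (rowRanges carry \code{summit}, \code{occupancy} and raw \code{totalCount}),
#' columns are titration samples (colData carries \code{sampleId},
#' \code{concentration}, \code{replicateLabel}, \code{spikeInFragments} and the
#' size-selected \code{libSize} used for CPM). \code{normState} tracks whether
#' the single \code{"counts"} assay holds raw integers, CPM, or spike-in scaled
#' values; \code{pseudocount} is set once scores are computed.
#'
#' @slot kind \code{"mono"} or \code{"sub"}.
#' @slot normState one of \code{"raw"}, \code{"cpm"}, \code{"spike"}.
#' @slot pseudocount regression pseudocount, \code{NA} until normalized.
#'
#' @export
setClass("NucCountMatrix",
    contains = "RangedSummarizedExperiment",
    representation(kind = "character",
                   normState = "character",
                   pseudocount = "numeric"))

setValidity("NucCountMatrix", function(object) {
    msg <- NULL
    if (!object@kind %in% c("mono", "sub"))
        msg <- c(msg, "kind must be 'mono' or 'sub'")
    if (!object@normState %in% c("raw", "cpm", "spike"))
        msg <- c(msg, "normState must be 'raw', 'cpm' or 'spike'")
    a <- SummarizedExperiment::assay(object, "counts")
    if (any(a < 0)) msg <- c(msg, "counts must be nonnegative")
    if (object@normState == "raw" && any(a != round(a)))
        msg <- c(msg, "raw counts must be integers")
    if (object@normState == "raw" && !is.na(object@pseudocount))
        msg <- c(msg, "pseudocount may only be set after normalization")
    need <- c("sampleId", "concentration", "libSize")
    if (!all(need %in% colnames(SummarizedExperiment::colData(object))))
        msg <- c(msg, "colData must carry sampleId, concentration, libSize")
    if (is.null(msg)) TRUE else msg
})

## ---------------------------------------------------------------------------
## ScoreTable
## ---------------------------------------------------------------------------

#' Per-position accessibility/stability scores
#'
#' The underlying \code{GRanges} carries metadata columns \code{gc},
#' \code{rawScore} (signed regression slope), \code{score} (GC-corrected
#' nucMACC or sub-nucMACC), \code{nConditions} (regression points used),
#' \code{totalCount} (raw fragment total across samples) and \code{label}
#' (classification, \code{NA} until classified).
#'
#' @slot positions annotated \code{GRanges}.
#' @slot kind \code{"mono"} (nucMACC) or \code{"sub"} (sub-nucMACC).
#'
#' @export
setClass("ScoreTable",
    representation(positions = "GRanges", kind = "character"))

setValidity("ScoreTable", function(object) {
    msg <- NULL
    if (!object@kind %in% c("mono", "sub"))
        msg <- c(msg, "kind must be 'mono' or 'sub'")
    need <- c("gc", "rawScore", "score", "nConditions", "totalCount", "label")
    if (!all(need %in% colnames(S4Vectors::mcols(object@positions))))
        msg <- c(msg, paste("positions must carry columns:",
                            paste(need, collapse = ", ")))
    if (is.null(msg)) TRUE else msg
})

#' @param positions annotated \code{GRanges} (see slot description).
#' @param kind \code{"mono"} or \code{"sub"}.
#' @return A \code{ScoreTable}.
#' @rdname ScoreTable-class
#' @export
ScoreTable <- function(positions, kind) {
    new("ScoreTable", positions = positions, kind = kind)
}

## ---------------------------------------------------------------------------
## CutoffResult
## ---------------------------------------------------------------------------

#' Result of the rank-slope cutoff procedure
#'
#' @slot lowCutoffRank normalized rank where the curve slope first falls below
#'   1 (\code{NA} if it never does).
#' @slot highCutoffRank normalized rank of the last upward slope-1 crossing
#'   (\code{NA} if none).
#' @slot lowSet integer indices (into the input score vector) of the low tail.
#' @slot highSet integer indices of the high tail.
#' @slot curve data.frame with \code{rank}, \code{normScore}, \code{fitted},
#'   \code{slope} over the sorted scores (diagnostic table).
#'
#' @export
setClass("CutoffResult",
    representation(lowCutoffRank = "numeric", highCutoffRank = "numeric",
                   lowSet = "integer", highSet = "integer",
                   curve = "data.frame"))

setValidity("CutoffResult", function(object) {
    if (length(intersect(object@lowSet, object@highSet)))
        "lowSet and highSet must be disjoint" else TRUE
})

## ---------------------------------------------------------------------------
## SimConfig
## ---------------------------------------------------------------------------

#' Configuration for a simulated MNase titration experiment
#'
#' See \code{\link{simulateExperiment}} for the generative model. Distribution
#' slots are functions of \code{n} returning \code{n} draws.
#'
#' @export
setClass("SimConfig",
    representation(nNucleosomes = "integer",
                   nChromosomes = "integer",
                   spacing = "numeric",
                   concentrations = "numeric",
                   replicates = "integer",
                   depth = "numeric",
                   accessibilityDist = "function",
                   stabilityDist = "function",
                   fragileFraction = "numeric",
                   subFractionWeight = "numeric",
                   baselineSubWeight = "numeric",
                   gcMean = "numeric",
                   gcSd = "numeric",
                   gcBiasBeta = "numeric",
                   monoLength = "numeric",
                   subLength = "numeric",
                   jitterSd = "numeric",
                   spikeIn = "numeric",
                   seed = "integer"))

setValidity("SimConfig", function(object) {
    msg <- NULL
    if (object@nNucleosomes < 1L) msg <- c(msg, "nNucleosomes must be >= 1")
    if (length(unique(object@concentrations)) < 2L ||
        any(object@concentrations <= 0))
        msg <- c(msg, "need >= 2 distinct positive concentrations")
    if (object@depth <= 0) msg <- c(msg, "depth must be > 0")
    if (length(object@spacing) != 2L || object@spacing[1L] > object@spacing[2L])
        msg <- c(msg, "spacing must be an increasing length-2 range")
    if (object@spacing[1L] < 150)
        msg <- c(msg, "spacing below the fragment midpoint support (150 bp)")
    if (object@fragileFraction < 0 || object@fragileFraction > 1)
        msg <- c(msg, "fragileFraction must be in [0, 1]")
    if (is.null(msg)) TRUE else msg
})

#' @param nNucleosomes number of planted nucleosomes.
#' @param nChromosomes number of simulated chromosomes.
#' @param spacing length-2 bp range for uniform nucleosome spacing.
#' @param concentrations MNase concentrations (U), >= 2 distinct.
#' @param replicates replicates per concentration.
#' @param depth expected mono fragments per nucleosome per sample at c = 1 U.
#' @param accessibilityDist function(n) drawing true accessibility a_i.
#' @param stabilityDist function(n) drawing true stability s_i.
#' @param fragileFraction fraction of nucleosomes that shed sub-nucleosomal
#'   fragments at high rate (the planted unstable-particle population).
#' @param subFractionWeight expected sub/mono fragment ratio at fragile sites.
#' @param baselineSubWeight expected sub/mono ratio at canonical sites.
#' @param gcMean,gcSd per-nucleosome target GC distribution (truncated normal).
#' @param gcBiasBeta concentration-coupled GC bias coefficient (0 = none).
#' @param monoLength,subLength mean and sd of fragment length normals.
#' @param jitterSd sd (bp) of fragment midpoint jitter around the dyad.
#' @param spikeIn per-sample spike-in fragment counts (recycled), or \code{NA}.
#' @param seed RNG seed; fixed seed gives byte-identical outputs.
#' @return A \code{SimConfig}.
#' @rdname SimConfig-class
#' @export
SimConfig <- function(nNucleosomes = 1000, nChromosomes = 1,
                      spacing = c(170, 200),
                      concentrations = c(1.5, 6.25, 25, 100),
                      replicates = 2, depth = 100,
                      accessibilityDist = function(n) stats::rnorm(n, 0, 0.2),
                      stabilityDist = function(n) stats::rnorm(n, 0, 0.2),
                      fragileFraction = 0.2, subFractionWeight = 2,
                      baselineSubWeight = 0.05,
                      gcMean = 0.45, gcSd = 0.08, gcBiasBeta = 0,
                      monoLength = c(160, 12), subLength = c(110, 15),
                      jitterSd = 10, spikeIn = NA_real_, seed = 1) {
    new("SimConfig", nNucleosomes = as.integer(nNucleosomes),
        nChromosomes = as.integer(nChromosomes), spacing = as.numeric(spacing),
        concentrations = as.numeric(concentrations),
        replicates = as.integer(replicates), depth = as.numeric(depth),
        accessibilityDist = accessibilityDist, stabilityDist = stabilityDist,
        fragileFraction = as.numeric(fragileFraction),
        subFractionWeight = as.numeric(subFractionWeight),
        baselineSubWeight = as.numeric(baselineSubWeight),
        gcMean = as.numeric(gcMean), gcSd = as.numeric(gcSd),
        gcBiasBeta = as.numeric(gcBiasBeta),
        monoLength = as.numeric(monoLength), subLength = as.numeric(subLength),
        jitterSd = as.numeric(jitterSd), spikeIn = as.numeric(spikeIn),
        seed = as.integer(seed))
}
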