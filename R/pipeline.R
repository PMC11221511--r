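## End-to-end orchestration of the titration analysis.

#' Run the full MNase titration analysis
#'
#' From a sample sheet of aligned fragment files over >= 2 MNase
#' concentrations to classified accessibility (nucMACC) and stability
#' (sub-nucMACC) score tables:
#' \enumerate{
#'   \item read fragments per sample (BAM or BED3), apply MAPQ and blacklist
#'     filters, split into mono ([140, 200) bp) and sub (< 140 bp) fractions;
#'   \item call mono-nucleosome positions from the pooled mono fragments of
#'     all samples, and sub-nucleosome positions from the sub fragments of
#'     the lowest-concentration sample(s), via midpoint-extension pileup;
#'   \item count fragment midpoints per position, drop low-count positions
#'     (mono total < 30, sub total < 5), normalize (CPM or spike-in), and
#'     regress log2 counts on log2 concentration with the median-of-medians
#'     pseudocount; nucMACC = -slope, sub-nucMACC = +slope;
#'   \item filter GC extremes, apply the LOESS GC correction;
#'   \item keep only informative sub positions (unique or >= fourfold the
#'     overlapping mono position's lowest-MNase normalized count), and label
#'     hypo-/hyper-accessible and unstable/noncanonical positions by the
#'     rank-slope cutoff.
#' }
#'
#' @param sampleSheet path to a sample sheet (see
#'   \code{\link{readSampleSheet}}) or an equivalent data.frame.
#' @param genome a \code{\link{GenomeInfo}} with \code{fastaPath} set.
#' @param blacklist optional \code{GRanges} of regions to exclude.
#' @param normalization \code{"cpm"} (default) or \code{"spike"}.
#' @param minMapq BAM mapping-quality cutoff.
#' @param monoRange mono-nucleosome length window (half-open).
#' @param subMin minimum sub-nucleosomal fragment length.
#' @param extension,width,minCenterDist,minHeight,smoothBp position-calling
#'   parameters, see \code{\link{midpointProfile}} and
#'   \code{\link{callPositions}}.
#' @param minMono,minSub count-filter thresholds.
#' @param span LOESS span for both GC correction and rank-slope cutoffs.
#' @param gcQuantiles length-2 GC-extremes filter quantiles.
#' @param fold informativeness ratio for sub positions.
#' @param minLoessN minimum positions for the GC LOESS fit.
#' @param classify run the rank-slope classification (default TRUE).
#' @return list with \code{mono} and \code{sub} (\code{\link{ScoreTable}}s,
#'   labeled when \code{classify}), \code{monoPositions},
#'   \code{subPositions} (informative) and \code{subPositionsAll}
#'   (\code{\link{PositionSet}}s), \code{counts} (normalized
#'   \code{\link{NucCountMatrix}} per fraction), and \code{qc} (FPN report,
#'   replicate correlations, fragment-size histograms).
#' @export
runNucMACC <- function(sampleSheet, genome, blacklist = NULL,
                       normalization = c("cpm", "spike"), minMapq = 30,
                       monoRange = c(140, 200), subMin = 0, extension = 70,
                       width = 147, minCenterDist = 120, minHeight = 0.5,
                       smoothBp = 21, minMono = 30, minSub = 5, span = 0.1,
                       gcQuantiles = c(0.01, 0.99), fold = 4,
                       minLoessN = 200, classify = TRUE) {
    normalization <- match.arg(normalization)
    sheet <- if (is.character(sampleSheet)) readSampleSheet(sampleSheet)
             else as.data.frame(sampleSheet)
    conc <- sheet$concentration_U
    if (length(unique(conc)) < 2L)
        stop("need >= 2 distinct MNase concentrations")
    if (max(conc) / min(conc) < 10)
        warning("concentration span under 10-fold (", max(conc) / min(conc),
                "x); scores may be unreliable")

    allSets <- vector("list", nrow(sheet))
    monoSets <- vector("list", nrow(sheet))
    subSets <- vector("list", nrow(sheet))
    sizeHist <- vector("list", nrow(sheet))
    names(sizeHist) <- sheet$sample_id
    for (i in seq_len(nrow(sheet))) {
        sm <- SampleMeta(sheet$sample_id[i], sheet$concentration_U[i],
                         sheet$replicate[i], sheet$spike_in_fragments[i])
        fs <- readFragments(sheet$path[i], genome, sm, minMapq = minMapq)
        fs <- excludeRegions(fs, blacklist)
        allSets[[i]] <- fs
        sizeHist[[i]] <- fragmentSizeHistogram(fs)
        split <- classifyBySize(fs, monoMin = monoRange[1L],
                                monoMax = monoRange[2L], subMin = subMin)
        monoSets[[i]] <- split$mono
        subSets[[i]] <- split$sub
    }
    lowest <- which(conc == min(conc))

    fpn <- fpnReport(
        nTotal = sum(vapply(allSets, nFragments, numeric(1))),
        nMono = sum(vapply(monoSets, nFragments, numeric(1))),
        nSubLowest = sum(vapply(subSets[lowest], nFragments, numeric(1))),
        genome = genome)

    ## position calling: mono from all samples pooled, sub from lowest MNase
    monoTrack <- midpointProfile(monoSets, genome, extension)
    monoPs <- callPositions(monoTrack, genome, "mono", width = width,
                            minCenterDist = minCenterDist,
                            minHeight = minHeight, smoothBp = smoothBp)
    subTrack <- midpointProfile(subSets[lowest], genome, extension)
    subPs <- callPositions(subTrack, genome, "sub", width = width,
                           minCenterDist = minCenterDist,
                           minHeight = minHeight, smoothBp = smoothBp)

    ## counting and normalization
    monoCmRaw <- countFragments(monoPs, monoSets)
    subCmRaw <- countFragments(subPs, subSets)
    ## informative sub positions: unique or >= fold x the overlapping mono's
    ## normalized lowest-MNase count. The rule always compares
    ## fraction-specific CPM (each fraction normalized by its own library),
    ## independent of the score normalization mode: a per-sample spike factor
    ## is common to both fractions and would reduce the rule to a raw-count
    ## ratio.
    monoNormFull <- normalizeCounts(monoCmRaw, "cpm")
    subNormFull <- normalizeCounts(subCmRaw, "cpm")
    lowCols <- function(cm) {
        a <- SummarizedExperiment::assay(cm, "counts")
        idx <- which(SummarizedExperiment::colData(cm)$concentration ==
                     min(conc))
        rowMeans(a[, idx, drop = FALSE])
    }
    keepInf <- selectInformativeSubnucs(subPs, monoPs, lowCols(subNormFull),
                                        lowCols(monoNormFull), fold = fold)
    if (any(!keepInf))
        message(sum(!keepInf), " uninformative sub position(s) removed ",
                "(neither unique nor >= ", fold, "-fold over mono)")
    subPsInf <- subPs[keepInf]

    monoCm <- normalizeCounts(filterLowCounts(monoCmRaw, minMono = minMono),
                              normalization)
    subCm <- normalizeCounts(filterLowCounts(subCmRaw[keepInf, ],
                                             minSub = minSub),
                             normalization)

    ## scoring
    gcOf <- function(cm) gcContent(
        PositionSet(SummarizedExperiment::rowRanges(cm), kind(cm)), genome)
    stMono <- scorePositions(monoCm, gcOf(monoCm), span = span,
                             gcLowQ = gcQuantiles[1L],
                             gcHighQ = gcQuantiles[2L], minLoessN = minLoessN)
    stSub <- scorePositions(subCm, gcOf(subCm), span = span,
                            gcLowQ = gcQuantiles[1L],
                            gcHighQ = gcQuantiles[2L], minLoessN = minLoessN)
    if (classify) {
        stMono <- classifyAccessibility(stMono, span = span)
        stSub <- classifyStability(stSub, span = span)
    }

    qc <- list(fpn = fpn,
               replicateCorrelation = suppressWarnings(
                   replicateCorrelation(monoCm)),
               sizeHistograms = sizeHist)
    list(mono = stMono, sub = stSub, monoPositions = monoPs,
         subPositions = subPsInf, subPositionsAll = subPs,
         counts = list(mono = monoCm, sub = subCm), qc = qc)
}
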