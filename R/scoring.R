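## Fragment counting, normalization, and regression scoring.

#' Count fragments per position per sample
#'
#' A fragment is assigned to a position when its midpoint falls inside the
#' position interval; a midpoint exactly at the (half-open) end coordinate is
#' not counted. When position intervals overlap (possible when
#' \code{minCenterDist < width}), a midpoint is assigned to the leftmost
#' overlapping position only, so every fragment contributes to at most one
#' position. The size-selected fragment total of each sample is recorded as
#' its library size (used for CPM); raw per-position totals are stored in
#' \code{rowData} as \code{totalCount}.
#'
#' @param ps a \code{\link{PositionSet}}.
#' @param fragmentSets list of \code{FragmentSet}s, one per sample, all of the
#'   fraction matching \code{kind(ps)}.
#' @return a \code{\link{NucCountMatrix}} with \code{normState = "raw"}.
#' @export
countFragments <- function(ps, fragmentSets) {
    stopifnot(is(ps, "PositionSet"))
    if (is(fragmentSets, "FragmentSet")) fragmentSets <- list(fragmentSets)
    fracs <- vapply(fragmentSets, fraction, character(1))
    if (any(fracs != kind(ps)))
        stop("fragment fraction does not match position kind '", kind(ps), "'")
    pos <- positions(ps)
    n <- length(pos)
    counts <- matrix(0L, nrow = n, ncol = length(fragmentSets))
    meta <- lapply(fragmentSets, sampleMeta)
    for (j in seq_along(fragmentSets)) {
        gr <- fragments(fragmentSets[[j]])
        if (length(gr) == 0L) next
        m0 <- .midpoints0(gr)
        mids <- GRanges(GenomicRanges::seqnames(gr),
                        IRanges(start = m0 + 1L, width = 1L))
        hit <- GenomicRanges::findOverlaps(mids, pos, select = "first",
                                           ignore.strand = TRUE)
        counts[, j] <- tabulate(hit[!is.na(hit)], nbins = n)
    }
    colnames(counts) <- vapply(meta, sampleId, character(1))
    cd <- S4Vectors::DataFrame(
        sampleId = vapply(meta, sampleId, character(1)),
        concentration = vapply(meta, concentration, numeric(1)),
        replicateLabel = vapply(meta, function(m) m@replicateLabel, character(1)),
        spikeInFragments = vapply(meta, spikeInFragments, numeric(1)),
        libSize = vapply(fragmentSets, nFragments, numeric(1)))
    rr <- pos
    S4Vectors::mcols(rr)$totalCount <- rowSums(counts)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts), rowRanges = rr, colData = cd)
    new("NucCountMatrix", se, kind = kind(ps), normState = "raw",
        pseudocount = NA_real_)
}

#' Remove positions with low total fragment counts
#'
#' A position is removed when its raw fragment total across all samples falls
#' below the threshold for its kind: \code{minMono} for mono-nucleosome
#' positions, \code{minSub} for sub-nucleosome positions ("less than" is
#' strict, so a total exactly at the threshold is kept).
#'
#' @param cm a raw \code{\link{NucCountMatrix}}.
#' @param minMono,minSub count thresholds (defaults 30 and 5).
#' @return the filtered \code{NucCountMatrix}.
#' @export
filterLowCounts <- function(cm, minMono = 30, minSub = 5) {
    stopifnot(is(cm, "NucCountMatrix"))
    if (normState(cm) != "raw")
        stop("filterLowCounts expects raw counts")
    thr <- if (kind(cm) == "mono") minMono else minSub
    totals <- rowSums(SummarizedExperiment::assay(cm, "counts"))
    keep <- totals >= thr
    if (!any(keep))
        stop("all ", kind(cm), " positions fall below the count threshold (",
             thr, "); nothing to score")
    if (any(!keep))
        message(sum(!keep), " ", kind(cm), " position(s) with total count < ",
                thr, " removed")
    cm[keep, ]
}

#' Normalize a count matrix
#'
#' \code{"cpm"} scales each sample by \code{1e6 / libSize}, where the library
#' size is the total number of size-selected fragments of that sample's
#' fraction (not just those assigned to positions). \code{"spike"} divides
#' each sample by its spike-in fragment count over one million.
#'
#' @param cm a raw \code{\link{NucCountMatrix}}.
#' @param mode \code{"cpm"} or \code{"spike"}.
#' @return the normalized \code{NucCountMatrix}.
#' @export
normalizeCounts <- function(cm, mode = c("cpm", "spike")) {
    mode <- match.arg(mode)
    stopifnot(is(cm, "NucCountMatrix"))
    if (normState(cm) != "raw")
        stop("counts are already normalized (", normState(cm), ")")
    a <- SummarizedExperiment::assay(cm, "counts")
    cd <- SummarizedExperiment::colData(cm)
    if (mode == "cpm") {
        if (any(cd$libSize <= 0)) stop("zero library size")
        a <- sweep(a, 2L, 1e6 / cd$libSize, `*`)
    } else {
        if (any(is.na(cd$spikeInFragments)))
            stop("spike normalization requires spikeInFragments for every sample")
        if (any(cd$spikeInFragments <= 0)) stop("zero spike-in fragment count")
        a <- sweep(a, 2L, cd$spikeInFragments / 1e6, `/`)
    }
    out <- cm
    SummarizedExperiment::assay(out, "counts", withDimnames = FALSE) <- a
    out@normState <- mode
    out
}

#' Regression pseudocount
#'
#' The pseudocount is the median over samples of the per-sample median
#' normalized count.
#'
#' @param cm a normalized \code{\link{NucCountMatrix}}.
#' @return the pseudocount (numeric scalar).
#' @export
computePseudocount <- function(cm) {
    stopifnot(is(cm, "NucCountMatrix"))
    if (normState(cm) == "raw")
        stop("pseudocount is computed on normalized counts")
    a <- SummarizedExperiment::assay(cm, "counts")
    if (nrow(a) == 0L || ncol(a) == 0L) stop("empty count matrix")
    stats::median(apply(a, 2L, stats::median))
}

#' Raw regression score for one position
#'
#' Ordinary least squares of \code{log2(value + pseudocount)} on
#' \code{log2(concentration)}. For mono-nucleosomes the nucMACC score is the
#' negated slope (positive = preferentially released at mild digestion); for
#' sub-nucleosomes the sub-nucMACC score is the slope itself (strongly
#' negative = unstable particle).
#'
#' @param values normalized counts for one position, one per sample.
#' @param concentrations MNase concentrations (U), same length; replicates at
#'   the same concentration enter as separate regression points.
#' @param pseudocount pseudocount added before the log transform.
#' @param kind \code{"mono"} or \code{"sub"}.
#' @return the raw score (numeric scalar).
#' @export
regressionScore <- function(values, concentrations, pseudocount,
                            kind = c("mono", "sub")) {
    kind <- match.arg(kind)
    if (length(values) != length(concentrations))
        stop("values and concentrations must have equal length")
    if (length(unique(concentrations)) < 2L)
        stop("need >= 2 distinct concentrations for the regression")
    x <- log2(concentrations)
    y <- log2(values + pseudocount)
    if (any(!is.finite(y)) || any(!is.finite(x)))
        stop("non-finite values in the regression inputs")
    m <- stats::lm.fit(cbind(1, x), y)$coefficients[[2L]]
    if (kind == "mono") -m else m
}

# vectorized slopes for a positions-x-samples matrix
.regressionSlopes <- function(mat, concentrations, pseudocount) {
    if (length(unique(concentrations)) < 2L)
        stop("need >= 2 distinct concentrations for the regression")
    y <- t(log2(mat + pseudocount))
    if (any(!is.finite(y))) stop("non-finite values in the regression inputs")
    fit <- stats::lm.fit(cbind(1, log2(concentrations)), y)
    co <- fit$coefficients
    if (is.matrix(co)) as.numeric(co[2L, ]) else co[[2L]]
}

#' Filter positions with rare extreme GC content
#'
#' Removes positions whose GC fraction falls below the \code{lowQ} or above
#' the \code{highQ} empirical quantile of the GC distribution. Degenerate
#' (constant) GC distributions are left untouched with a warning.
#'
#' @param st a \code{\link{ScoreTable}}.
#' @param lowQ,highQ quantile bounds (defaults 0.01 and 0.99).
#' @return the filtered \code{ScoreTable}.
#' @export
gcFilter <- function(st, lowQ = 0.01, highQ = 0.99) {
    stopifnot(is(st, "ScoreTable"))
    if (!(lowQ >= 0 && lowQ < 0.5 && highQ > 0.5 && highQ <= 1))
        stop("lowQ must be in [0, 0.5), highQ in (0.5, 1]")
    g <- gcFraction(st)
    if (length(unique(g)) <= 1L) {
        warning("degenerate GC distribution; gcFilter is a no-op")
        return(st)
    }
    q <- stats::quantile(g, c(lowQ, highQ), na.rm = TRUE, names = FALSE)
    keep <- g >= q[1L] & g <= q[2L]
    st[keep]
}

#' LOESS GC-bias correction
#'
#' Fits a local regression (degree-2 polynomial, tricube weights, no
#' robustness iterations) of the raw scores on GC content with span
#' \code{span}, and subtracts each position's deviation of the fit from the
#' median raw score: \code{corrected = raw - (L(gc) - median(raw))}. With
#' fewer than \code{minPositions} positions the fit is unstable and the
#' correction is skipped with a warning.
#'
#' @param rawScores numeric vector of raw scores.
#' @param gc matching GC fractions.
#' @param span LOESS smoothing parameter alpha (default 0.1).
#' @param minPositions minimum positions for a stable fit (default 200).
#' @return corrected scores, same length and order as \code{rawScores}.
#' @export
loessGcCorrect <- function(rawScores, gc, span = 0.1, minPositions = 200) {
    if (length(rawScores) != length(gc))
        stop("rawScores and gc must have equal length")
    if (length(rawScores) < minPositions) {
        warning("fewer than ", minPositions,
                " positions; GC correction skipped")
        return(rawScores)
    }
    fit <- stats::loess(rawScores ~ gc, span = span, degree = 2,
                        family = "gaussian")
    L <- stats::fitted(fit)
    rawScores - (L - stats::median(rawScores))
}

#' Score positions of a count matrix
#'
#' One-stop scoring: computes (or accepts) the pseudocount, regresses
#' log2-transformed normalized counts on log2 concentration for every
#' position, applies the GC-extremes filter and the LOESS GC correction, and
#' returns a \code{\link{ScoreTable}}. Positions with undefined GC (\code{NA})
#' are dropped first.
#'
#' @param cm a normalized \code{\link{NucCountMatrix}}.
#' @param gc GC fractions for the rows of \code{cm} (from
#'   \code{\link{gcContent}} on the same positions).
#' @param span LOESS span for the GC correction.
#' @param gcLowQ,gcHighQ GC-extremes filter quantiles.
#' @param minLoessN minimum positions for the LOESS fit.
#' @param pseudocount optional fixed pseudocount; computed from \code{cm} when
#'   \code{NULL}.
#' @return a \code{ScoreTable} (kind inherited from \code{cm}).
#' @export
scorePositions <- function(cm, gc, span = 0.1, gcLowQ = 0.01, gcHighQ = 0.99,
                           minLoessN = 200, pseudocount = NULL) {
    stopifnot(is(cm, "NucCountMatrix"))
    if (normState(cm) == "raw")
        stop("normalize the count matrix before scoring")
    if (length(gc) != nrow(cm))
        stop("gc must have one value per count-matrix row")
    ok <- !is.na(gc)
    if (any(!ok)) {
        message(sum(!ok), " position(s) without defined GC dropped")
        cm <- cm[ok, ]
        gc <- gc[ok]
    }
    p <- pseudocount %||% computePseudocount(cm)
    a <- SummarizedExperiment::assay(cm, "counts")
    conc <- SummarizedExperiment::colData(cm)$concentration
    slopes <- .regressionSlopes(a, conc, p)
    raw <- if (kind(cm) == "mono") -slopes else slopes
    gr <- SummarizedExperiment::rowRanges(cm)
    mc <- S4Vectors::mcols(gr)
    mc$gc <- gc
    mc$rawScore <- raw
    mc$score <- NA_real_
    mc$nConditions <- ncol(a)
    if (is.null(mc$totalCount)) mc$totalCount <- rowSums(a)
    mc$label <- NA_character_
    S4Vectors::mcols(gr) <- mc
    st <- ScoreTable(gr, kind(cm))
    st <- gcFilter(st, gcLowQ, gcHighQ)
    gr <- positions(st)
    S4Vectors::mcols(gr)$score <- loessGcCorrect(
        S4Vectors::mcols(gr)$rawScore, S4Vectors::mcols(gr)$gc,
        span = span, minPositions = minLoessN)
    S4Vectors::metadata(gr)$pseudocount <- p
    ScoreTable(gr, kind(cm))
}

#' Write a score table as TSV
#'
#' Columns: chrom, start (0-based), end, summit (0-based), gc, rawScore,
#' score, nConditions, totalCount, label.
#'
#' @param st a \code{ScoreTable}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeScores <- function(st, path) {
    gr <- positions(st)
    mc <- S4Vectors::mcols(gr)
    dt <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                     start = GenomicRanges::start(gr) - 1L,
                     end = GenomicRanges::end(gr),
                     summit = mc$summit - 1L,
                     gc = mc$gc,
                     rawScore = mc$rawScore,
                     score = mc$score,
                     nConditions = mc$nConditions,
                     totalCount = mc$totalCount,
                     label = mc$label)
    data.table::fwrite(dt, path, sep = "\t", col.names = TRUE)
    invisible(path)
}
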