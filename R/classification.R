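## Rank-slope cutoff selection and position classification.

#' Rank-slope cutoffs on a score distribution
#'
#' Scores are sorted ascending and placed on a unit square: x = rank divided
#' by the number of scores, y = score rescaled so the full range spans 1. A
#' LOESS fit of y on x is differentiated by central finite differences, and
#' the unit slope defines the cutoffs: the low tail contains the positions
#' before the slope first falls below 1 (empty when the curve starts flatter
#' than the diagonal), the high tail contains the positions from the last
#' upward crossing of slope 1 onwards. The same geometric rule is used to
#' call super-enhancers from ranked enhancer signal.
#'
#' @param scores numeric score vector (>= 100 values recommended; the range
#'   must be nonzero).
#' @param span LOESS span (default 0.1).
#' @return a \code{\link{CutoffResult}}; \code{lowSet}/\code{highSet} index
#'   into \code{scores}.
#' @export
rankSlopeCutoffs <- function(scores, span = 0.1) {
    n <- length(scores)
    if (n < 10L) stop("too few scores for the rank-slope procedure")
    if (n < 100L)
        warning("fewer than 100 scores; cutoffs may be unstable")
    rng <- max(scores) - min(scores)
    if (rng == 0) stop("zero score range; cutoffs undefined")
    o <- order(scores)
    x <- seq_len(n) / n
    y <- (scores[o] - min(scores)) / rng
    f <- stats::fitted(stats::loess(y ~ x, span = span, degree = 2,
                                    family = "gaussian"))
    slope <- numeric(n)
    slope[1L] <- (f[2L] - f[1L]) / (x[2L] - x[1L])
    slope[n] <- (f[n] - f[n - 1L]) / (x[n] - x[n - 1L])
    mid <- 2:(n - 1L)
    slope[mid] <- (f[mid + 1L] - f[mid - 1L]) / (x[mid + 1L] - x[mid - 1L])

    # tolerance so an exactly-diagonal curve (slope == 1 up to rounding)
    # yields empty tails instead of noise-driven cutoffs
    eps <- 1e-8
    below <- which(slope < 1 - eps)
    if (length(below) == 0L) {
        warning("slope never falls below 1; low set empty")
        k1 <- NA_integer_
        lowIdx <- integer(0)
    } else {
        k1 <- below[1L]
        lowIdx <- if (k1 > 1L) o[seq_len(k1 - 1L)] else integer(0)
    }
    up <- slope > 1 + eps
    crossUp <- which(up[-1L] & !up[-n]) + 1L
    if (length(crossUp) == 0L) {
        if (length(below) > 0L)
            warning("slope never exceeds 1 again; high set empty")
        k2 <- NA_integer_
        highIdx <- integer(0)
    } else {
        k2 <- crossUp[length(crossUp)]
        highIdx <- o[k2:n]
    }
    new("CutoffResult",
        lowCutoffRank = if (is.na(k1)) NA_real_ else x[k1],
        highCutoffRank = if (is.na(k2)) NA_real_ else x[k2],
        lowSet = as.integer(lowIdx), highSet = as.integer(highIdx),
        curve = data.frame(rank = x, normScore = y, fitted = f, slope = slope))
}

.labelFromCutoffs <- function(n, cr, lowLabel, highLabel) {
    lab <- rep("none", n)
    lab[cr@lowSet] <- lowLabel
    lab[cr@highSet] <- highLabel
    lab
}

#' @describeIn classifyAccessibility label a numeric nucMACC score vector;
#'   returns a character vector ("hypo"/"hyper"/"none").
#' @export
setMethod("classifyAccessibility", "numeric", function(x, ...) {
    cr <- rankSlopeCutoffs(x, ...)
    .labelFromCutoffs(length(x), cr, "hypo", "hyper")
})

#' @describeIn classifyAccessibility label a mono \code{ScoreTable}
#'   (hypo-/hyper-accessible); the \code{CutoffResult} is stored in the
#'   table's metadata under \code{"cutoffs"}.
#' @export
setMethod("classifyAccessibility", "ScoreTable", function(x, ...) {
    if (kind(x) != "mono")
        stop("accessibility classification applies to mono-nucleosome scores")
    cr <- rankSlopeCutoffs(scores(x), ...)
    gr <- positions(x)
    S4Vectors::mcols(gr)$label <- .labelFromCutoffs(length(gr), cr,
                                                    "hypo", "hyper")
    S4Vectors::metadata(gr)$cutoffs <- cr
    ScoreTable(gr, "mono")
})

#' @describeIn classifyAccessibility label a numeric sub-nucMACC score vector
#'   ("unstable"/"noncanonical"/"none").
#' @export
setMethod("classifyStability", "numeric", function(x, ...) {
    cr <- rankSlopeCutoffs(x, ...)
    .labelFromCutoffs(length(x), cr, "unstable", "noncanonical")
})

#' @describeIn classifyAccessibility label a sub \code{ScoreTable}
#'   (unstable/noncanonical).
#' @export
setMethod("classifyStability", "ScoreTable", function(x, ...) {
    if (kind(x) != "sub")
        stop("stability classification applies to sub-nucleosome scores")
    cr <- rankSlopeCutoffs(scores(x), ...)
    gr <- positions(x)
    S4Vectors::mcols(gr)$label <- .labelFromCutoffs(length(gr), cr,
                                                    "unstable", "noncanonical")
    S4Vectors::metadata(gr)$cutoffs <- cr
    ScoreTable(gr, "sub")
})

#' Cutoff diagnostics stored on a classified ScoreTable
#'
#' @param st a classified \code{ScoreTable}.
#' @return the stored \code{\link{CutoffResult}}, or \code{NULL}.
#' @export
scoreCutoffs <- function(st) {
    stopifnot(is(st, "ScoreTable"))
    S4Vectors::metadata(positions(st))$cutoffs
}

#' Select informative sub-nucleosome positions
#'
#' A sub-nucleosome position is informative when it is unique (overlaps no
#' mono-nucleosome position by even 1 bp) or carries at least
#' \code{fold}-fold more normalized fragment counts in the lowest-MNase
#' condition than the mono-nucleosome it overlaps ("at least" is inclusive:
#' a ratio of exactly \code{fold} is retained). When several mono positions
#' overlap, the comparison is against the one with the largest overlap (ties
#' toward the leftmost).
#'
#' @param subPs sub \code{\link{PositionSet}}.
#' @param monoPs mono \code{\link{PositionSet}}.
#' @param subCountsLowest normalized lowest-MNase sub counts, one per sub
#'   position (fraction-specific normalization).
#' @param monoCountsLowest normalized lowest-MNase mono counts, one per mono
#'   position.
#' @param fold minimum sub/mono ratio (default 4).
#' @return logical vector, \code{TRUE} for retained sub positions.
#' @export
selectInformativeSubnucs <- function(subPs, monoPs, subCountsLowest,
                                     monoCountsLowest, fold = 4) {
    stopifnot(is(subPs, "PositionSet"), is(monoPs, "PositionSet"))
    sub <- positions(subPs)
    mono <- positions(monoPs)
    if (length(subCountsLowest) != length(sub) ||
        length(monoCountsLowest) != length(mono))
        stop("counts must match the position sets")
    hits <- GenomicRanges::findOverlaps(sub, mono, ignore.strand = TRUE)
    keep <- rep(TRUE, length(sub))
    if (length(hits) == 0L) return(keep)
    ovWidth <- GenomicRanges::width(GenomicRanges::pintersect(
        sub[S4Vectors::queryHits(hits)], mono[S4Vectors::subjectHits(hits)]))
    # per sub position, the mono partner with the largest overlap
    ord <- order(S4Vectors::queryHits(hits), -ovWidth,
                 S4Vectors::subjectHits(hits))
    q <- S4Vectors::queryHits(hits)[ord]
    s <- S4Vectors::subjectHits(hits)[ord]
    first <- !duplicated(q)
    partner <- s[first]
    covered <- q[first]
    keep[covered] <- subCountsLowest[covered] >=
        fold * monoCountsLowest[partner]
    keep
}

#' Classify promoters by upstream unstable particles
#'
#' A TSS is labeled \code{"unstable_promoter"} when the summit of any
#' unstable position lies within the strand-oriented window
#' \code{[TSS - upstream, TSS + downstream]} (both ends inclusive), and
#' \code{"NDR_promoter"} otherwise. The default window (200 bp upstream,
#' 0 downstream) suits compact genomes; a (150, 50) window is the common
#' alternative for mammalian promoters.
#'
#' @param tss stranded \code{GRanges} of transcription start sites (the TSS is
#'   the 5' end of each range; strand must be "+" or "-").
#' @param unstable \code{\link{PositionSet}} (or \code{ScoreTable}) of
#'   unstable positions; summits are used.
#' @param upstream,downstream window extents in bp.
#' @return \code{DataFrame} with \code{label} and \code{distance} (bp from
#'   the TSS to the nearest unstable summit; \code{NA} if none exists).
#' @export
classifyPromoters <- function(tss, unstable, upstream = 200, downstream = 0) {
    if (is(unstable, "ScoreTable")) {
        gr <- positions(unstable)
        lab <- S4Vectors::mcols(gr)$label
        if (any(!is.na(lab))) gr <- gr[!is.na(lab) & lab == "unstable"]
        summit <- S4Vectors::mcols(gr)$summit
        chr <- as.character(GenomicRanges::seqnames(gr))
    } else if (is(unstable, "PositionSet")) {
        summit <- summits(unstable)
        chr <- as.character(GenomicRanges::seqnames(positions(unstable)))
    } else stop("unstable must be a PositionSet or ScoreTable")
    strand <- as.character(GenomicRanges::strand(tss))
    if (any(strand == "*"))
        stop("promoter classification requires stranded TSS")
    tssPos <- ifelse(strand == "+", GenomicRanges::start(tss),
                     GenomicRanges::end(tss))
    winStart <- ifelse(strand == "+", tssPos - upstream, tssPos - downstream)
    winEnd <- ifelse(strand == "+", tssPos + downstream, tssPos + upstream)
    win <- GRanges(GenomicRanges::seqnames(tss),
                   IRanges(start = winStart, end = winEnd))
    summitGr <- GRanges(chr, IRanges(start = summit, width = 1L))
    hit <- IRanges::overlapsAny(win, summitGr, ignore.strand = TRUE)
    tssGr <- GRanges(GenomicRanges::seqnames(tss),
                     IRanges(start = tssPos, width = 1L))
    dist <- rep(NA_integer_, length(tss))
    if (length(summitGr)) {
        near <- GenomicRanges::distanceToNearest(tssGr, summitGr,
                                                 ignore.strand = TRUE)
        dist[S4Vectors::queryHits(near)] <- S4Vectors::mcols(near)$distance
    }
    S4Vectors::DataFrame(
        label = ifelse(hit, "unstable_promoter", "NDR_promoter"),
        distance = dist, row.names = names(tss))
}

#' Plot the rank-slope diagnostic curve
#'
#' Normalized scores against normalized ranks, with the LOESS fit and the
#' unit-slope cutoffs.
#'
#' @param cr a \code{\link{CutoffResult}}.
#' @param ... passed to \code{plot}.
#' @return invisibly, \code{cr}.
#' @export
plotRankCurve <- function(cr, ...) {
    cv <- cutoffCurve(cr)
    plot(cv$rank, cv$normScore, pch = 16, cex = 0.3, col = "grey50",
         xlab = "normalized rank", ylab = "normalized score", ...)
    graphics::lines(cv$rank, cv$fitted, col = "black", lwd = 2)
    if (!is.na(cr@lowCutoffRank))
        graphics::abline(v = cr@lowCutoffRank, col = "purple", lty = 2)
    if (!is.na(cr@highCutoffRank))
        graphics::abline(v = cr@highCutoffRank, col = "darkgreen", lty = 2)
    invisible(cr)
}
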