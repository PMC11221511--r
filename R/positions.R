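## Position calling from midpoint-extension pileups, and per-position GC.

#' Midpoint-extension coverage profile
#'
#' Each fragment is reduced to its midpoint and extended to \code{extension}
#' bp (floor/ceil split for odd extensions); the per-base pileup of these
#' intervals is scaled by \code{G / (N * extension)}, where \code{G} is the
#' effective genome size and \code{N} the total number of fragments, so that
#' the genome-wide mean coverage over the effective genome equals 1. Several
#' fragment sets (e.g. all mono fractions of a titration) are pooled before
#' pileup.
#'
#' @param fragmentSets a \code{FragmentSet} or list of \code{FragmentSet}s,
#'   all of the same fraction.
#' @param genome a \code{\link{GenomeInfo}}.
#' @param extension extension width in bp (default 70).
#' @return an \code{RleList} coverage track (one run-length vector per
#'   chromosome); \code{metadata()} records \code{nFragments}, \code{scale}
#'   and \code{fraction}.
#' @export
midpointProfile <- function(fragmentSets, genome, extension = 70) {
    if (is(fragmentSets, "FragmentSet")) fragmentSets <- list(fragmentSets)
    fracs <- unique(vapply(fragmentSets, fraction, character(1)))
    if (length(fracs) > 1L)
        stop("all fragment sets must share the same fraction; got: ",
             paste(fracs, collapse = ", "))
    grl <- lapply(fragmentSets, fragments)
    gr <- do.call(c, grl)
    si <- .seqinfo(genome)
    if (length(gr) == 0L) {
        warning("no fragments; returning an all-zero track")
        empty <- GRanges(seqinfo = si)
        track <- GenomicRanges::coverage(empty)
        S4Vectors::metadata(track) <- list(nFragments = 0L, scale = NA_real_,
                                           fraction = fracs %||% "all")
        return(track)
    }
    m0 <- .midpoints0(gr)
    left <- extension %/% 2L
    right <- extension - left
    ext <- GRanges(GenomicRanges::seqnames(gr),
                   IRanges(start = m0 - left + 1L, end = m0 + right),
                   seqinfo = si)
    ext <- GenomicRanges::trim(ext)
    scale <- effectiveGenomeSize(genome) / (length(gr) * extension)
    track <- GenomicRanges::coverage(ext) * scale
    S4Vectors::metadata(track) <- list(nFragments = length(gr), scale = scale,
                                       fraction = fracs)
    track
}

#' Call nucleosome positions from a coverage track
#'
#' Candidate summits are the local maxima of the moving-average-smoothed
#' track with smoothed height at least \code{minHeight} (in units of the
#' genome-average coverage). Summits are accepted greedily in order of
#' decreasing height -- ties broken toward the smaller coordinate -- subject
#' to a minimum pairwise center distance within each chromosome. Each
#' accepted summit yields a fixed-width interval centered on it, clipped at
#' chromosome edges.
#'
#' @param track coverage \code{RleList} from \code{\link{midpointProfile}}.
#' @param genome a \code{\link{GenomeInfo}}.
#' @param kind \code{"mono"} or \code{"sub"}; recorded on the result.
#' @param width position width in bp (default 147, the core-particle length).
#' @param minCenterDist minimum distance between accepted summits (bp).
#' @param minHeight minimum normalized smoothed height (default 0.5).
#' @param smoothBp moving-average window (bp; coerced to odd, default 21).
#' @return a \code{\link{PositionSet}} sorted by coordinate.
#' @export
callPositions <- function(track, genome, kind = c("mono", "sub"), width = 147,
                          minCenterDist = 120, minHeight = 0.5, smoothBp = 21) {
    kind <- match.arg(kind)
    stopifnot(width > 0, minCenterDist > 0)
    si <- .seqinfo(genome)
    chroms <- names(chromSizes(genome))
    resChrom <- character(0); resSummit <- integer(0); resHeight <- numeric(0)
    for (chr in intersect(chroms, names(track))) {
        v <- as.numeric(track[[chr]])
        if (length(v) == 0L || all(v == 0)) next
        s <- .runmean(v, smoothBp)
        cand <- .localMaxima(s)
        cand <- cand[s[cand] >= minHeight]
        if (length(cand) == 0L) next
        o <- order(-s[cand], cand)
        cand <- cand[o]
        accepted <- integer(0)
        for (p in cand) {
            if (length(accepted) == 0L ||
                min(abs(accepted - p)) >= minCenterDist)
                accepted <- c(accepted, p)
        }
        resChrom <- c(resChrom, rep(chr, length(accepted)))
        resSummit <- c(resSummit, accepted)
        resHeight <- c(resHeight, s[accepted])
    }
    if (length(resSummit) == 0L) {
        warning("flat track: no positions called")
        gr <- GRanges(seqinfo = si)
        S4Vectors::mcols(gr)$summit <- integer(0)
        S4Vectors::mcols(gr)$occupancy <- numeric(0)
        return(PositionSet(gr, kind))
    }
    halfL <- width %/% 2L
    chromLen <- chromSizes(genome)[resChrom]
    start1 <- pmax(1L, resSummit - halfL)
    end1 <- pmin(as.integer(chromLen), resSummit - halfL + as.integer(width) - 1L)
    gr <- GRanges(resChrom, IRanges(start = start1, end = end1), seqinfo = si)
    S4Vectors::mcols(gr)$summit <- resSummit
    S4Vectors::mcols(gr)$occupancy <- resHeight
    gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
    PositionSet(gr, kind)
}

#' GC content at called positions
#'
#' The GC fraction of each position interval is \code{(#G + #C) / (#A + #C +
#' #G + #T)}; ambiguous bases are excluded from the denominator. Positions
#' with all-ambiguous sequence get \code{NA} (and are excluded from scoring
#' downstream).
#'
#' @param ps a \code{\link{PositionSet}}.
#' @param genome a \code{\link{GenomeInfo}} with \code{fastaPath} set; the
#'   FASTA is indexed on first use.
#' @return numeric vector of GC fractions in [0, 1], one per position.
#' @export
gcContent <- function(ps, genome) {
    stopifnot(is(ps, "PositionSet"))
    fa <- fastaPath(genome)
    if (is.na(fa) || !file.exists(fa))
        stop("gcContent requires a genome FASTA (GenomeInfo fastaPath)")
    if (!file.exists(paste0(fa, ".fai"))) Rsamtools::indexFa(fa)
    gr <- positions(ps)
    if (length(gr) == 0L) return(numeric(0))
    seqs <- Rsamtools::scanFa(fa, gr)
    af <- Biostrings::letterFrequency(seqs, letters = c("A", "C", "G", "T"))
    denom <- rowSums(af)
    gc <- (af[, "G"] + af[, "C"]) / denom
    nBad <- sum(denom == 0)
    if (nBad > 0L)
        message(nBad, " position(s) with all-ambiguous sequence flagged (NA GC)")
    as.numeric(gc)
}

#' Write called positions as BED6+
#'
#' Columns: chrom, start, end, name, occupancy, strand ("."), summit
#' (0-based).
#'
#' @param ps a \code{PositionSet}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writePositionsBed <- function(ps, path) {
    gr <- positions(ps)
    dt <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                     start = GenomicRanges::start(gr) - 1L,
                     end = GenomicRanges::end(gr),
                     name = paste0(kind(ps), "_", seq_along(gr)),
                     score = round(S4Vectors::mcols(gr)$occupancy, 4),
                     strand = ".",
                     summit = S4Vectors::mcols(gr)$summit - 1L)
    data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
    invisible(path)
}
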