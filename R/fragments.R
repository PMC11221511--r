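## Fragment input, filtering and size classification.

#' Read a sample sheet
#'
#' The sample sheet is a TSV/CSV with columns \code{sample_id}, \code{path},
#' \code{concentration_U}, \code{replicate} and optionally
#' \code{spike_in_fragments}. Relative paths are resolved against the sheet's
#' directory.
#'
#' @param path path to the sheet (delimiter inferred from the extension:
#'   \code{.csv} is comma, anything else tab).
#' @return a data.frame with one row per sample.
#' @export
readSampleSheet <- function(path) {
    if (!file.exists(path)) stop("sample sheet not found: ", path)
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    sheet <- utils::read.table(path, header = TRUE, sep = sep,
                               stringsAsFactors = FALSE)
    need <- c("sample_id", "path", "concentration_U", "replicate")
    miss <- setdiff(need, colnames(sheet))
    if (length(miss))
        stop("sample sheet misses column(s): ", paste(miss, collapse = ", "))
    if (anyDuplicated(sheet$sample_id))
        stop("sample_id values must be unique")
    if (any(sheet$concentration_U <= 0))
        stop("concentrations must be positive")
    if (!"spike_in_fragments" %in% colnames(sheet))
        sheet$spike_in_fragments <- NA_real_
    rel <- !grepl("^(/|[A-Za-z]:)", sheet$path)
    sheet$path[rel] <- file.path(dirname(path), sheet$path[rel])
    sheet
}

#' Read a BED file of genomic regions
#'
#' Thin wrapper over \code{rtracklayer::import} for blacklists and TSS lists.
#'
#' @param path a BED file.
#' @return a \code{GRanges}.
#' @export
readRegionsBed <- function(path) {
    rtracklayer::import(path, format = "BED")
}

#' Read aligned paired-end fragments
#'
#' Builds a \code{\link{FragmentSet}} (fraction \code{"all"}) from either a
#' coordinate-sorted, indexed paired-end BAM or a BED3 file of fragment
#' intervals. For BAM input one fragment is emitted per properly paired
#' template, spanning from the leftmost mate start to the rightmost mate end;
#' templates whose leftmost alignment has mapping quality below \code{minMapq}
#' are removed. BED rows pass through unchanged (0-based half-open converted
#' to the 1-based GRanges representation). Fragments on chromosomes absent
#' from \code{genome}, and malformed zero/negative-length records, are dropped
#' with a message.
#'
#' @param path input file.
#' @param genome a \code{\link{GenomeInfo}}.
#' @param sample a \code{\link{SampleMeta}} describing the sample.
#' @param format \code{"auto"} (by extension), \code{"bam"} or \code{"bed"}.
#' @param minMapq minimum mapping quality for BAM templates (default 30).
#' @return a \code{FragmentSet} with \code{fraction = "all"}.
#' @export
readFragments <- function(path, genome, sample,
                          format = c("auto", "bam", "bed"), minMapq = 30) {
    format <- match.arg(format)
    if (!file.exists(path)) stop("cannot read fragment file: ", path)
    if (format == "auto")
        format <- if (grepl("\\.bam$", path, ignore.case = TRUE)) "bam" else "bed"
    if (format == "bam") {
        df <- .readBamTemplates(path, minMapq)
    } else {
        df <- .readBed3(path)
    }
    nBad <- sum(df$end <= df$start)
    if (nBad > 0L) {
        message(nBad, " zero/negative-length record(s) rejected")
        df <- df[df$end > df$start, , drop = FALSE]
    }
    known <- df$chrom %in% names(chromSizes(genome))
    if (any(!known)) {
        message(sum(!known), " fragment(s) on chromosomes absent from the ",
                "genome dropped")
        df <- df[known, , drop = FALSE]
    }
    gr <- GRanges(df$chrom,
                  IRanges(start = df$start + 1L, end = df$end),
                  seqinfo = .seqinfo(genome))
    if (length(gr) == 0L)
        warning("no fragments retained from ", path)
    FragmentSet(gr, sample, fraction = "all")
}

# BED3 as a 0-based half-open data.frame; extra columns ignored
.readBed3 <- function(path) {
    dt <- data.table::fread(path, header = FALSE, select = 1:3,
                            col.names = c("chrom", "start", "end"),
                            colClasses = list(character = 1),
                            data.table = FALSE, showProgress = FALSE)
    dt
}

# properly paired templates from a BAM: leftmost mate (TLEN > 0) spans the pair
.readBamTemplates <- function(path, minMapq) {
    param <- Rsamtools::ScanBamParam(
        flag = Rsamtools::scanBamFlag(isPaired = TRUE, isProperPair = TRUE,
                                      isUnmappedQuery = FALSE,
                                      isSecondaryAlignment = FALSE),
        what = c("rname", "pos", "isize", "mapq"))
    res <- Rsamtools::scanBam(path, param = param)[[1L]]
    keepLeft <- !is.na(res$isize) & res$isize > 0L
    if (!any(keepLeft)) {
        warning("BAM contains no properly paired templates: ", path)
        return(data.frame(chrom = character(0), start = integer(0),
                          end = integer(0)))
    }
    mapq <- res$mapq[keepLeft]
    mapq[is.na(mapq)] <- 0L
    keepQ <- mapq >= minMapq
    if (any(!keepQ))
        message(sum(!keepQ), " template(s) below MAPQ ", minMapq, " removed")
    data.frame(chrom = as.character(res$rname[keepLeft][keepQ]),
               start = res$pos[keepLeft][keepQ] - 1L,
               end = res$pos[keepLeft][keepQ] - 1L + res$isize[keepLeft][keepQ])
}

#' Split fragments into mono- and sub-nucleosomal fractions
#'
#' Mono-nucleosomal fragments have lengths in the half-open window
#' \code{[monoMin, monoMax)}; sub-nucleosomal fragments are shorter than
#' \code{monoMin} (and at least \code{subMin}, a guard against adapter-length
#' artifacts). Fragments of length \code{>= monoMax} (di-nucleosomes and
#' larger) are discarded with a message, as are sub fragments below
#' \code{subMin}.
#'
#' @param fs a \code{FragmentSet} with \code{fraction = "all"}.
#' @param monoMin,monoMax mono-nucleosome length window (bp), default [140, 200).
#' @param subMin minimum sub-nucleosomal length (bp), default 0.
#' @return list with elements \code{mono} and \code{sub} (both
#'   \code{FragmentSet}s) and \code{nDiscarded} (fragments outside both
#'   windows).
#' @export
classifyBySize <- function(fs, monoMin = 140, monoMax = 200, subMin = 0) {
    stopifnot(is(fs, "FragmentSet"))
    if (monoMin >= monoMax) stop("monoMin must be < monoMax")
    gr <- fragments(fs)
    w <- GenomicRanges::width(gr)
    isMono <- w >= monoMin & w < monoMax
    isSub <- w < monoMin & w >= subMin
    nDiscarded <- sum(!isMono & !isSub)
    if (nDiscarded > 0L)
        message(nDiscarded, " fragment(s) outside [", subMin, ", ", monoMax,
                ") discarded")
    list(mono = FragmentSet(gr[isMono], fs@sample, "mono",
                            sizeRange = c(monoMin, monoMax)),
         sub = FragmentSet(gr[isSub], fs@sample, "sub",
                           sizeRange = c(subMin, monoMin)),
         nDiscarded = nDiscarded)
}

#' Remove fragments overlapping blacklisted regions
#'
#' A fragment is removed if it overlaps any blacklist interval by at least
#' 1 bp; intervals that merely touch end-to-start (half-open adjacency) do not
#' overlap.
#'
#' @param fs a \code{FragmentSet}.
#' @param blacklist a \code{GRanges} of regions to exclude (e.g. read from a
#'   BED file with \code{rtracklayer::import}), or \code{NULL} for identity.
#' @return the filtered \code{FragmentSet}.
#' @export
excludeRegions <- function(fs, blacklist) {
    stopifnot(is(fs, "FragmentSet"))
    if (is.null(blacklist) || length(blacklist) == 0L) return(fs)
    gr <- fragments(fs)
    hit <- IRanges::overlapsAny(gr, blacklist, ignore.strand = TRUE)
    if (any(hit))
        message(sum(hit), " fragment(s) overlapping blacklisted regions removed")
    FragmentSet(gr[!hit], fs@sample, fs@fraction, fs@sizeRange)
}

#' Write fragments as BED3
#'
#' @param fs a \code{FragmentSet}.
#' @param path output path (0-based half-open BED3).
#' @return the path, invisibly.
#' @export
writeFragmentsBed <- function(fs, path) {
    gr <- fragments(fs)
    dt <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                     start = GenomicRanges::start(gr) - 1L,
                     end = GenomicRanges::end(gr))
    data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
    invisible(path)
}
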