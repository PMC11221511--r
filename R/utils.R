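## Internal numeric helpers.

# centered moving average with edge-shrunk windows; k coerced to odd
.runmean <- function(v, k) {
    k <- as.integer(k)
    if (k <= 1L) return(v)
    h <- k %/% 2L
    n <- length(v)
    cs <- cumsum(c(0, v))
    i <- seq_len(n)
    lo <- pmax(1L, i - h)
    hi <- pmin(n, i + h)
    (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# leftmost index of every strict local-maximum plateau
.localMaxima <- function(s) {
    r <- rle(s)
    nr <- length(r$values)
    if (nr == 0L) return(integer(0))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    left <- c(-Inf, r$values[-nr])
    right <- c(r$values[-1L], -Inf)
    starts[r$values > left & r$values > right]
}

.seqinfo <- function(genome) {
    GenomeInfoDb::Seqinfo(seqnames = names(chromSizes(genome)),
                          seqlengths = as.integer(chromSizes(genome)))
}

# 0-based fragment midpoint, as used for pileup and count assignment
.midpoints0 <- function(gr) {
    (GenomicRanges::start(gr) - 1L + GenomicRanges::end(gr)) %/% 2L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
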