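test_that("fragment midpoints are tallied into half-open positions", {
    genome <- testGenome(c(chrT = 5000))
    ps <- makePositions(1001, width = 147)   # 0-based [1000, 1147)
    # five fragments with midpoints inside
    fs <- makeFragments(c(1000, 1010, 1020, 1030, 1040),
                        c(1100, 1110, 1120, 1130, 1140),
                        genome = genome, fraction = "mono")
    cm <- countFragments(ps, fs)
    expect_equal(as.numeric(SummarizedExperiment::assay(cm)), 5)
    # midpoint exactly at the end coordinate (0-based 1147) is not counted
    fsEdge <- makeFragments(c(1143, 1142), c(1151, 1150), genome = genome,
                            fraction = "mono")
    cmE <- countFragments(ps, fsEdge)
    expect_equal(as.numeric(SummarizedExperiment::assay(cmE)), 1)
    # fraction mismatch is a configuration error
    expect_error(countFragments(ps, makeFragments(1, 100, genome = genome,
                                                  fraction = "sub")),
                 "does not match")
})

test_that("midpoint counting matches a brute-force tally", {
    genome <- testGenome(c(chrT = 20000))
    starts1 <- seq(1001, by = 1500, length.out = 10)
    ps <- makePositions(starts1, width = 147)
    set.seed(13)
    s0 <- sample(0:19000, 200, replace = TRUE)
    e0 <- s0 + sample(100:180, 200, replace = TRUE)
    fs <- makeFragments(s0, pmin(e0, 20000), genome = genome,
                        fraction = "mono")
    cm <- countFragments(ps, fs)
    mids0 <- (s0 + pmin(e0, 20000)) %/% 2
    oracle <- vapply(starts1, function(st)
        sum(mids0 >= st - 1 & mids0 < st - 1 + 147), numeric(1))
    expect_equal(as.numeric(SummarizedExperiment::assay(cm)), oracle)
    # library size is the fragment total of the set, not the assigned total
    expect_equal(SummarizedExperiment::colData(cm)$libSize, 200)
})

test_that("low-count filtering is strict-below per kind", {
    counts <- cbind(c(10, 10, 2), c(19, 20, 2))   # totals 29, 30, 4
    cm <- toyCountMatrix(counts, conc = c(1.5, 100))
    kept <- quietly(filterLowCounts(cm))
    expect_equal(nrow(kept), 1L)
    expect_equal(as.numeric(SummarizedExperiment::assay(kept)[1, ]), c(10, 20))

    cmSub <- toyCountMatrix(cbind(c(2, 3), c(2, 2)), conc = c(1.5, 100),
                            kind = "sub")                    # totals 4, 5
    keptSub <- quietly(filterLowCounts(cmSub))
    expect_equal(nrow(keptSub), 1L)
    # zero thresholds are the identity
    expect_equal(nrow(filterLowCounts(cm, minMono = 0, minSub = 0)), 3L)
    # everything filtered is a hard error
    expect_error(quietly(filterLowCounts(toyCountMatrix(
        cbind(1, 1), conc = c(1.5, 100)))), "nothing to score")
})

test_that("CPM and spike normalization follow their definitions", {
    cm <- toyCountMatrix(cbind(c(50, 10), c(100, 20)), conc = c(1.5, 100),
                         libSize = c(1e6, 2e6), spike = c(2e6, 4e6))
    cpm <- normalizeCounts(cm, "cpm")
    expect_equal(SummarizedExperiment::assay(cpm)[1, ], c(s1 = 50, s2 = 50))
    expect_equal(normState(cpm), "cpm")
    sp <- normalizeCounts(cm, "spike")
    expect_equal(SummarizedExperiment::assay(sp)[1, ], c(s1 = 25, s2 = 25))
    expect_error(normalizeCounts(cpm, "cpm"), "already normalized")
    noSpike <- toyCountMatrix(cbind(1:2, 1:2), conc = c(1.5, 100))
    expect_error(normalizeCounts(noSpike, "spike"), "requires spikeInFragments")
})

test_that("spike-in proportional to library size cancels in the slope", {
    set.seed(21)
    counts <- matrix(rpois(400, 60), ncol = 4)
    lib <- c(2e5, 3e5, 2.5e5, 4e5)
    cm <- toyCountMatrix(counts, conc = c(1.5, 6.25, 25, 100), libSize = lib,
                         spike = lib * 10)
    cpm <- normalizeCounts(cm, "cpm")
    sp <- normalizeCounts(cm, "spike")
    pC <- computePseudocount(cpm)
    pS <- computePseudocount(sp)
    x <- log2(c(1.5, 6.25, 25, 100))
    slopeOf <- function(a, p) apply(a, 1, function(v)
        stats::coef(stats::lm(log2(v + p) ~ x))[[2]])
    sC <- slopeOf(SummarizedExperiment::assay(cpm), pC)
    sS <- slopeOf(SummarizedExperiment::assay(sp), pS)
    expect_lt(max(abs(sC - sS)), 1e-9)
})

test_that("the pseudocount is the median of sample medians", {
    cm <- toyCountMatrix(matrix(c(10, 10, 10, 20, 20, 20, 30, 30, 30),
                                ncol = 3),
                         conc = c(1.5, 25, 100))
    expect_equal(computePseudocount(normalizeCounts(cm, "cpm")), 20)
    # single sample: its own median
    one <- toyCountMatrix(matrix(c(3, 7, 11), ncol = 1), conc = 1.5)
    expect_equal(computePseudocount(normalizeCounts(one, "cpm")), 7)
    # random matrix vs a naive two-level oracle
    set.seed(4)
    m <- matrix(rpois(400, 30), ncol = 4)
    cm4 <- toyCountMatrix(m, conc = c(1.5, 6.25, 25, 100),
                          libSize = rep(1e6, 4))
    expect_equal(computePseudocount(normalizeCounts(cm4, "cpm")),
                 median(apply(m, 2, median)))
    expect_error(computePseudocount(cm4), "normalized")
})

test_that("regression scores follow the OLS slope and sign convention", {
    conc <- c(1, 2, 4, 8)
    # flat values: slope 0 for both kinds
    expect_equal(regressionScore(rep(32, 4), conc, 1, "mono"), 0)
    expect_equal(regressionScore(rep(32, 4), conc, 1, "sub"), 0)
    # exact line: log2(v + 0) = {10, 9, 8, 7} over log2 c = {0,1,2,3}
    v <- 2^c(10, 9, 8, 7)
    expect_equal(regressionScore(v, conc, 0, "mono"), 1)
    expect_equal(regressionScore(v, conc, 0, "sub"), -1)
    # errors
    expect_error(regressionScore(c(1, 2), c(5, 5), 1, "mono"),
                 "distinct concentrations")
    expect_error(regressionScore(c(-2, 1), c(1, 8), 1, "mono"), "non-finite")
})

test_that("regression matches the closed-form OLS slope to 10 digits", {
    set.seed(31)
    conc <- c(1.5, 6.25, 25, 100)
    x <- log2(conc)
    for (i in 1:50) {
        v <- runif(4, 1, 1000)
        p <- runif(1, 0, 50)
        y <- log2(v + p)
        oracle <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
        got <- regressionScore(v, conc, p, "sub")
        expect_lt(abs(got - oracle) / max(abs(oracle), 1e-12), 1e-10)
        # sign convention: mono score is the negated sub score
        expect_equal(regressionScore(v, conc, p, "mono"), -got)
    }
})

test_that("raising counts only at the highest concentration lowers nucMACC", {
    conc <- c(1.5, 6.25, 25, 100)
    v <- c(100, 90, 80, 70)
    base <- regressionScore(v, conc, 5, "mono")
    bumped <- regressionScore(c(100, 90, 80, 90), conc, 5, "mono")
    expect_lt(bumped, base)
})

test_that("scaling one sample's counts and library together cancels", {
    set.seed(8)
    counts <- matrix(rpois(40, 50), ncol = 4)
    lib <- rep(2e5, 4)
    cm1 <- toyCountMatrix(counts, conc = c(1.5, 6.25, 25, 100), libSize = lib)
    counts2 <- counts
    counts2[, 2] <- counts2[, 2] * 7
    cm2 <- toyCountMatrix(counts2, conc = c(1.5, 6.25, 25, 100),
                          libSize = c(lib[1], lib[2] * 7, lib[3:4]))
    expect_equal(SummarizedExperiment::assay(normalizeCounts(cm1, "cpm")),
                 SummarizedExperiment::assay(normalizeCounts(cm2, "cpm")))
})

test_that("GC-extremes filtering trims the stated quantiles", {
    makeSt <- function(g) {
        gr <- positions(makePositions(seq(1, by = 300, length.out = length(g))))
        S4Vectors::mcols(gr) <- cbind(S4Vectors::mcols(gr),
            S4Vectors::DataFrame(gc = g, rawScore = 0, score = 0,
                                 nConditions = 4L, totalCount = 100,
                                 label = NA_character_))
        ScoreTable(gr, "mono")
    }
    set.seed(17)
    g <- runif(1000)
    st <- makeSt(g)
    out <- gcFilter(st)
    q <- quantile(g, c(0.01, 0.99), names = FALSE)
    expect_equal(length(out), sum(g >= q[1] & g <= q[2]))
    expect_equal(length(gcFilter(st, 0, 1)), 1000L)
    # one extreme outlier among a tight cluster is removed
    g2 <- c(rnorm(500, 0.4, 0.01), 1.0)
    expect_false(1.0 %in% gcFraction(gcFilter(makeSt(g2))))
    # degenerate distribution: warn, no-op
    expect_warning(same <- gcFilter(makeSt(rep(0.4, 300))), "degenerate")
    expect_equal(length(same), 300L)
})

test_that("LOESS GC correction removes injected bias, preserves the median", {
    set.seed(23)
    n <- 5000
    g <- pmin(0.8, pmax(0.2, rnorm(n, 0.45, 0.08)))
    s <- rnorm(n, 0, 0.2)
    # bias-removal oracle: raw = s + beta * g with s independent of g
    raw <- s + 1 * g
    corr <- loessGcCorrect(raw, g)
    expect_gt(abs(cor(raw, g)), 0.3)
    expect_lt(abs(cor(corr, g)), 0.05)
    expect_lt(abs(median(corr) - median(raw)), 0.02)
    # no-bias limit: correction is nearly the identity
    raw0 <- rnorm(2000, 0, 0.2)
    g0 <- runif(2000, 0.2, 0.8)
    corr0 <- loessGcCorrect(raw0, g0)
    expect_lt(mean(abs(corr0 - raw0)), 0.05)
    # too few positions: skipped with warning, scores returned unchanged
    rawFew <- rnorm(50)
    expect_warning(same <- loessGcCorrect(rawFew, runif(50)), "skipped")
    expect_identical(same, rawFew)
})
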