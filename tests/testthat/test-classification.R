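## independent pointwise-scan oracle for the rank-slope rule
rankSlopeOracle <- function(scores, span = 0.1) {
    n <- length(scores)
    o <- order(scores)
    x <- seq_len(n) / n
    y <- (scores[o] - min(scores)) / (max(scores) - min(scores))
    f <- stats::fitted(stats::loess(y ~ x, span = span, degree = 2))
    slope <- numeric(n)
    for (i in seq_len(n)) {
        lo <- max(1, i - 1); hi <- min(n, i + 1)
        slope[i] <- (f[hi] - f[lo]) / (x[hi] - x[lo])
    }
    low <- integer(0)
    for (i in seq_len(n)) {
        if (slope[i] < 1 - 1e-8) { if (i > 1) low <- o[1:(i - 1)]; break }
    }
    high <- integer(0)
    k2 <- NA
    for (i in 2:n)
        if (slope[i] > 1 + 1e-8 && !(slope[i - 1] > 1 + 1e-8)) k2 <- i
    if (!is.na(k2)) high <- o[k2:n]
    list(low = low, high = high)
}

heavyTailScores <- function(n, seed = 11, extremes = 0.05) {
    set.seed(seed)
    nx <- round(n * extremes / 2)
    lab <- sample(c(rep("low", nx), rep("high", nx), rep("mid", n - 2 * nx)))
    x <- ifelse(lab == "low", rnorm(n, -1.5, 0.2),
                ifelse(lab == "high", rnorm(n, 1.5, 0.2), rnorm(n, 0, 0.2)))
    list(scores = x, lab = lab)
}

test_that("a perfectly linear score curve yields empty tails", {
    x <- seq_len(500) / 500
    expect_warning(cr <- rankSlopeCutoffs(x), "never")
    expect_equal(length(lowSet(cr)), 0L)
    expect_equal(length(highSet(cr)), 0L)
    expect_error(rankSlopeCutoffs(rep(1, 500)), "zero score range")
})

test_that("heavy-tailed scores produce tails containing the global extremes", {
    hs <- heavyTailScores(2000)
    cr <- rankSlopeCutoffs(hs$scores)
    expect_gt(length(lowSet(cr)), 0L)
    expect_gt(length(highSet(cr)), 0L)
    expect_true(which.min(hs$scores) %in% lowSet(cr))
    expect_true(which.max(hs$scores) %in% highSet(cr))
    expect_length(intersect(lowSet(cr), highSet(cr)), 0L)
})

test_that("cutoff sets match the pointwise slope-scan oracle", {
    for (seed in c(11, 99)) {
        hs <- heavyTailScores(2000, seed = seed)
        cr <- rankSlopeCutoffs(hs$scores)
        orc <- rankSlopeOracle(hs$scores)
        expect_setequal(lowSet(cr), orc$low)
        expect_setequal(highSet(cr), orc$high)
    }
})

test_that("labels are invariant under positive affine score transforms", {
    hs <- heavyTailScores(1500, seed = 5)
    base <- classifyAccessibility(hs$scores)
    expect_identical(classifyAccessibility(hs$scores + 3.7), base)
    expect_identical(classifyAccessibility(hs$scores * 2.5 - 1), base)
})

test_that("planted extreme populations are recovered with high sensitivity", {
    hs <- heavyTailScores(10000, seed = 42, extremes = 0.05)
    lab <- classifyAccessibility(hs$scores)
    expect_gte(mean(lab[hs$lab == "low"] == "hypo"), 0.8)
    expect_gte(mean(lab[hs$lab == "high"] == "hyper"), 0.8)
    # stability labeling uses the same geometry
    labS <- classifyStability(hs$scores)
    expect_gte(mean(labS[hs$lab == "low"] == "unstable"), 0.8)
    expect_length(intersect(which(labS == "unstable"),
                            which(labS == "noncanonical")), 0L)
})

test_that("unimodal score distributions keep extreme classes a minority", {
    for (seed in 1:3) {
        set.seed(seed)
        sc <- 0.2 * rt(2000, df = 5)
        lab <- classifyAccessibility(sc)
        expect_lt(mean(lab != "none"), 0.25)
    }
})

test_that("ScoreTable classification attaches labels and cutoffs", {
    hs <- heavyTailScores(1000, seed = 2)
    gr <- positions(makePositions(seq(1, by = 300, length.out = 1000)))
    S4Vectors::mcols(gr) <- cbind(S4Vectors::mcols(gr),
        S4Vectors::DataFrame(gc = runif(1000), rawScore = hs$scores,
                             score = hs$scores, nConditions = 4L,
                             totalCount = 100, label = NA_character_))
    st <- ScoreTable(gr, "mono")
    out <- classifyAccessibility(st)
    expect_identical(classLabels(out), classifyAccessibility(hs$scores))
    expect_s4_class(scoreCutoffs(out), "CutoffResult")
    expect_error(classifyStability(st), "sub-nucleosome")
})

test_that("informative sub positions are unique or >= fourfold over mono", {
    sub <- makePositions(c(1, 1000, 2000, 3000), width = 147, kind = "sub")
    mono <- makePositions(c(950, 1990, 2990), width = 147, kind = "mono")
    # sub 1 unique; sub 2..4 overlap mono 1..3
    keep <- selectInformativeSubnucs(sub, mono,
                                     subCountsLowest = c(5, 40, 39, 8),
                                     monoCountsLowest = c(10, 10, 2))
    expect_equal(keep, c(TRUE, TRUE, FALSE, TRUE))   # 4.0x kept, 3.9x dropped
    # monotone in fold: larger fold retains a subset
    keep8 <- selectInformativeSubnucs(sub, mono, c(5, 40, 39, 8),
                                      c(10, 10, 2), fold = 8)
    expect_true(all(which(keep8) %in% which(keep)))
})

test_that("largest-overlap mono partner is used and a brute force agrees", {
    set.seed(19)
    subStarts <- sample(seq(1, 14000, by = 40), 20)
    monoStarts <- sample(seq(1, 14000, by = 70), 10)
    sub <- makePositions(subStarts, width = 147, kind = "sub")
    mono <- makePositions(monoStarts, width = 147, kind = "mono")
    sc <- runif(20, 0, 50)
    mc <- runif(10, 1, 20)
    keep <- selectInformativeSubnucs(sub, mono, sc, mc)
    oracle <- vapply(seq_len(20), function(i) {
        s1 <- subStarts[i]; e1 <- s1 + 146
        ov <- pmax(0, pmin(e1, monoStarts + 146) - pmax(s1, monoStarts) + 1)
        if (all(ov == 0)) return(TRUE)
        j <- which.max(ov)
        sc[i] >= 4 * mc[j]
    }, logical(1))
    expect_equal(keep, oracle)
    expect_true(all(which(keep) %in% seq_len(20)))
})

test_that("promoters are classified in strand-oriented windows", {
    tss <- GenomicRanges::GRanges("chrT",
        IRanges::IRanges(start = c(5000, 6000), width = 1),
        strand = c("+", "-"))
    # unstable summit 150 bp upstream of the plus-strand TSS
    up <- makePositions(c(5000 - 150 - 73, 6000 + 150 - 73), width = 147,
                        kind = "sub")
    res <- classifyPromoters(tss, up, upstream = 200, downstream = 0)
    expect_equal(res$label, c("unstable_promoter", "unstable_promoter"))
    # the same geometry with a (150, 50) preset misses a 150-bp-upstream
    # summit on neither side (still inside 150)
    res2 <- classifyPromoters(tss, up, upstream = 150, downstream = 50)
    expect_equal(res2$label, c("unstable_promoter", "unstable_promoter"))
    # summit 180 bp upstream is outside the (150, 50) window
    up2 <- makePositions(5000 - 180 - 73, width = 147, kind = "sub")
    res3 <- classifyPromoters(tss[1], up2, upstream = 150, downstream = 50)
    expect_equal(res3$label, "NDR_promoter")
    expect_error(classifyPromoters(
        GenomicRanges::GRanges("chrT", IRanges::IRanges(5000, width = 1)),
        up), "stranded")
})

test_that("promoter classification matches a window-membership oracle", {
    set.seed(29)
    tssPos <- sample(2000:48000, 50)
    strand <- sample(c("+", "-"), 50, replace = TRUE)
    tss <- GenomicRanges::GRanges("chrT",
        IRanges::IRanges(start = tssPos, width = 1), strand = strand)
    summitPos <- sample(2000:48000, 20)
    up <- makePositions(summitPos - 73, width = 147, kind = "sub")
    for (win in list(c(200, 0), c(150, 50))) {
        res <- classifyPromoters(tss, up, upstream = win[1],
                                 downstream = win[2])
        oracle <- vapply(seq_len(50), function(i) {
            d <- if (strand[i] == "+") summitPos - tssPos[i]
                 else tssPos[i] - summitPos
            any(d >= -win[1] & d <= win[2])
        }, logical(1))
        expect_equal(res$label == "unstable_promoter", oracle)
    }
})
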