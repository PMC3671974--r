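# Region quantification, the exact binomial differential test, BH
# control, quartiles and group summaries.

test_that("regionHeight forces the documented arithmetic", {
    gi <- smallGenome(10000L)
    # one tag whose fragment covers the region, library of 10 tags
    lib <- libFromPositions(c(5000L, seq(100L, 900L, by = 100L)),
                            rep("+", 10L), gi)
    region <- GRanges("chr1", IRanges(5050L, 5080L), seqinfo = gi)
    expect_equal(regionHeight(region, lib), 1e6 / 10)
    # region with no overlapping fragments
    far <- GRanges("chr1", IRanges(9000L, 9100L), seqinfo = gi)
    expect_equal(regionHeight(far, lib), 0)
    # empty library warns and returns 0
    empty <- new("TagLibrary", tags = GRanges(seqinfo = gi),
                 replicateId = "e", condition = "c",
                 deduplicated = TRUE)
    expect_warning(h <- regionHeight(region, empty), "empty library")
    expect_equal(h, 0)
})

test_that("regionHeight and countTags equal the brute-force pileup on
           random fixtures", {
    gi <- smallGenome(5000L)
    set.seed(31)
    for (i in 1:40) {
        n <- sample(20:60, 1L)
        pos <- sample.int(5000L, n, replace = TRUE)
        str <- sample(c("+", "-"), n, replace = TRUE)
        lib <- libFromPositions(pos, str, gi)
        s <- sample.int(4500L, 1L); e <- s + sample.int(400L, 1L)
        region <- GRanges("chr1", IRanges(s, e), seqinfo = gi)
        td <- tagDf(tags(lib))
        depth <- oraclePileup(td, 108L, 5000L)
        expect_equal(regionHeight(region, lib),
                     max(depth[s:e]) * 1e6 / n)
        expect_equal(countTags(region, lib),
                     oracleFragmentCount(td, 108L, s, e, 5000L))
    }
})

test_that("heights are invariant under duplicating the library (RPM
           normalization)", {
    gi <- smallGenome(5000L)
    set.seed(37)
    lib <- libFromPositions(sample.int(5000L, 50L, replace = TRUE),
                            sample(c("+", "-"), 50L, replace = TRUE),
                            gi)
    doubled <- poolLibraries(list(lib, lib))
    region <- GRanges("chr1", IRanges(2000L, 2400L), seqinfo = gi)
    expect_equal(regionHeight(region, doubled),
                 regionHeight(region, lib))
})

test_that("differentialTest matches exact binomial enumeration", {
    # symmetric counts at equal depths
    r <- differentialTest(c(3L, 2L), c(2L, 3L), c(1e5, 1e5),
                          c(1e5, 1e5))
    expect_equal(r$pvalue, 1)
    # 10 vs 0 at equal depths: p = 2 / 2^10
    r <- differentialTest(10L, 0L, 1e5, 1e5)
    expect_equal(r$pvalue, 2 / 2^10)
    # all-zero counts flagged degenerate with p = 1
    r <- differentialTest(0L, 0L, 1e5, 1e5)
    expect_true(r$degenerate)
    expect_equal(r$pvalue, 1)
    # unequal depths shift the expected proportion
    r <- differentialTest(30L, 10L, 3e5, 1e5)
    expect_equal(r$expected_prop, 0.75)
    expect_gt(r$pvalue, 0.5)
})

test_that("bhAdjust implements step-up BH with monotone flags", {
    a <- bhAdjust(rep(1, 10))
    expect_false(any(a$significant))
    a <- bhAdjust(c(0.01, 0.02, 0.03, 0.5), fdr = 0.10)
    # direct step-up: q = (0.04, 0.04, 0.04, 0.5)
    expect_equal(a$qvalue, c(0.04, 0.04, 0.04, 0.5))
    expect_equal(sum(a$significant), 3L)
    a <- bhAdjust(0.04, fdr = 0.10)
    expect_true(a$significant)
    expect_equal(a$qvalue, 0.04)
    expect_error(bhAdjust(c(0.1, NaN)), "finite")
    # 10,000 random p-vectors against the reference implementation
    set.seed(41)
    maxDiff <- 0
    for (i in 1:10000) {
        p <- runif(sample(1:12, 1L))
        maxDiff <- max(maxDiff, abs(bhAdjust(p)$qvalue - oracleBH(p)))
    }
    expect_lt(maxDiff, 1e-12)
})

test_that("assignQuartiles balances sizes and matches a sort oracle", {
    expect_equal(assignQuartiles(c(1, 2, 3, 4)), 1:4)
    expect_warning(q <- assignQuartiles(c(1, 2, 3)), "single stratum")
    expect_equal(q, rep(1L, 3))
    # degenerate ties: deterministic, sizes within 1 of n/4
    q <- assignQuartiles(rep(5, 10))
    expect_identical(q, assignQuartiles(rep(5, 10)))
    expect_true(all(abs(table(q) - 2.5) <= 1.5))
    expect_true(all(diff(q) >= 0))
    # 1,000 random heights: membership matches a sort-based oracle
    set.seed(43)
    h <- runif(1000L)
    q <- assignQuartiles(h)
    oracle <- as.integer(ceiling(4 * rank(h, ties.method = "first")
                                 / 1000L))
    expect_identical(q, oracle)
    expect_true(all(h[q == 1L] <= min(h[q == 4L])))
})

test_that("mergeConditionPeaks consolidates, quantifies and filters", {
    gi <- smallGenome(50000L)
    set.seed(47)
    # strong site at 10,000 called in both conditions; site at 30,000
    # called only in 'fasted' but bound in both (comparable heights)
    mkLib <- function(id, cond) {
        pos <- c(9900L + sample.int(200L, 300L, replace = TRUE),
                 29900L + sample.int(200L, 280L, replace = TRUE),
                 sample.int(50000L, 1000L, replace = TRUE))
        libFromPositions(pos, sample(c("+", "-"), length(pos),
                                     replace = TRUE), gi,
                         id = id, cond = cond)
    }
    libs <- c(lapply(1:2, function(i) mkLib(paste0("rep", i),
                                            "fasted")),
              lapply(1:2, function(i) mkLib(paste0("rep", i),
                                            "refed")))
    mkPeak <- function(starts, src) {
        gr <- GRanges("chr1", IRanges(starts, starts + 300L),
                      seqinfo = gi)
        mcols(gr) <- S4Vectors::DataFrame(
            id = sprintf("%s_%d", src, seq_along(gr)),
            summit = starts + 150L, height_rpm = 1,
            pvalue = 1e-9, qvalue = 1e-6)
        new("PeakSet", peaks = gr, source = src,
            callerConfig = callerConfig())
    }
    fasted <- mkPeak(c(9850L, 29850L), "fasted")
    refed <- mkPeak(9850L, "refed")
    se <- suppressWarnings(mergeConditionPeaks(fasted, refed, libs,
                              heightThreshold = 0.35))
    rd <- SummarizedExperiment::rowData(se)
    expect_equal(nrow(se), 2L)
    expect_setequal(rd$origin, c("both", "fasted-only"))
    # the fasted-only region still carries comparable re-fed signal
    fOnly <- which(rd$origin == "fasted-only")
    expect_gt(rd$mean_b[fOnly], 0.35)
    expect_lt(abs(rd$log2_ratio[fOnly]), 1)
    # identical single-peak sets give one region of origin 'both'
    one <- suppressWarnings(mergeConditionPeaks(
        mkPeak(9850L, "fasted"), mkPeak(9850L, "refed"), libs))
    expect_equal(nrow(one), 1L)
    expect_equal(SummarizedExperiment::rowData(one)$origin, "both")
})

test_that("the height threshold filter equals a direct recomputation
           oracle", {
    gi <- smallGenome(50000L)
    set.seed(53)
    libs <- c(lapply(1:2, function(i) libFromPositions(
            sample.int(50000L, 2000L, replace = TRUE),
            sample(c("+", "-"), 2000L, replace = TRUE), gi,
            id = paste0("rep", i), cond = "fasted")),
        lapply(1:2, function(i) libFromPositions(
            sample.int(50000L, 2000L, replace = TRUE),
            sample(c("+", "-"), 2000L, replace = TRUE), gi,
            id = paste0("rep", i), cond = "refed")))
    starts <- seq(1000L, 46000L, by = 5000L)
    gr <- GRanges("chr1", IRanges(starts, starts + 250L),
                  seqinfo = gi)
    mcols(gr) <- S4Vectors::DataFrame(
        id = sprintf("p%d", seq_along(gr)),
        summit = starts + 125L, height_rpm = 1, pvalue = 0.001,
        qvalue = 0.01)
    ps <- new("PeakSet", peaks = gr, source = "fasted",
              callerConfig = callerConfig())
    ps2 <- new("PeakSet", peaks = gr, source = "refed",
               callerConfig = callerConfig())
    thr <- 180   # RPM, straddles the background heights here
    se <- mergeConditionPeaks(ps, ps2, libs, heightThreshold = thr)
    # oracle: recompute per-region average heights directly
    avg <- (rowMeans(cbind(regionHeight(gr, libs[[1]]),
                           regionHeight(gr, libs[[2]]))) +
            rowMeans(cbind(regionHeight(gr, libs[[3]]),
                           regionHeight(gr, libs[[4]])))) / 2
    expect_equal(nrow(se), sum(avg > thr))
    # quantification is call-set independent: swapping the origin
    # labels leaves all heights identical
    seSwap <- mergeConditionPeaks(ps2, ps, libs,
                                  heightThreshold = thr)
    expect_equal(SummarizedExperiment::assay(se, "height_rpm"),
                 SummarizedExperiment::assay(seSwap, "height_rpm"))
})

test_that("differentialBinding flags regions at the requested FDR", {
    gi <- smallGenome(50000L)
    set.seed(59)
    mkLib <- function(id, cond, extra) {
        pos <- c(9900L + sample.int(200L, extra, replace = TRUE),
                 sample.int(50000L, 800L, replace = TRUE))
        libFromPositions(pos, sample(c("+", "-"), length(pos),
                                     replace = TRUE), gi,
                         id = id, cond = cond)
    }
    libs <- c(lapply(1:3, function(i) mkLib(paste0("r", i), "fasted",
                                            400L)),
              lapply(1:3, function(i) mkLib(paste0("r", i), "refed",
                                            50L)))
    gr <- GRanges("chr1", IRanges(c(9850L, 30000L),
                                  c(10150L, 30300L)), seqinfo = gi)
    mcols(gr) <- S4Vectors::DataFrame(
        id = c("p1", "p2"), summit = start(gr) + 150L,
        height_rpm = 1, pvalue = 1e-6, qvalue = 1e-4)
    ps <- new("PeakSet", peaks = gr, source = "fasted",
              callerConfig = callerConfig())
    se <- suppressWarnings(mergeConditionPeaks(ps, ps, libs,
                                               heightThreshold = 0))
    dr <- differentialBinding(se, fdr = 0.10)
    expect_true(dr$significant[dr$id ==
        SummarizedExperiment::rowData(se)$id[1]])
    expect_false(dr$significant[2])
    expect_true(all(dr$qvalue >= dr$pvalue - 1e-12))
})

test_that("groupHeightSummary reports five-number summaries per
           group", {
    gi <- smallGenome(50000L)
    set.seed(61)
    libs <- c(lapply(1:2, function(i) libFromPositions(
            sample.int(50000L, 1500L, replace = TRUE),
            sample(c("+", "-"), 1500L, replace = TRUE), gi,
            id = paste0("r", i), cond = "fasted")),
        lapply(1:2, function(i) libFromPositions(
            sample.int(50000L, 1500L, replace = TRUE),
            sample(c("+", "-"), 1500L, replace = TRUE), gi,
            id = paste0("r", i), cond = "refed")))
    starts <- seq(2000L, 47000L, by = 3000L)
    gr <- GRanges("chr1", IRanges(starts, starts + 200L),
                  seqinfo = gi)
    mcols(gr) <- S4Vectors::DataFrame(
        id = sprintf("p%d", seq_along(gr)),
        summit = starts + 100L, height_rpm = 1, pvalue = 0.01,
        qvalue = 0.05)
    ps <- new("PeakSet", peaks = gr, source = "fasted",
              callerConfig = callerConfig())
    se <- mergeConditionPeaks(ps, ps, libs, heightThreshold = 0)
    grp <- rep(c("g1", "g2"), length.out = nrow(se))
    s <- groupHeightSummary(se, grp)
    rd <- SummarizedExperiment::rowData(se)
    # symmetric conditions: median log2 ratio near 0
    med <- s$median[s$group == "g1" & s$statistic == "log2_ratio"]
    expect_lt(abs(med), 0.5)
    # percentile oracle per group
    for (g in c("g1", "g2")) {
        expect_equal(
            s$median[s$group == g & s$statistic == "avg_height"],
            unname(stats::quantile(rd$avg_height[grp == g], 0.5)))
    }
    # empty group reported with n = 0
    s2 <- groupHeightSummary(se, factor(grp,
                                        levels = c("g1", "g2", "g3")))
    expect_equal(unique(s2$n[s2$group == "g3"]), 0L)
})

test_that("dispersion inflation softens the binomial test", {
    set.seed(67)
    m <- matrix(rpois(300L, 50) * sample(1:3, 300L, replace = TRUE),
                ncol = 3L)
    phi <- estimateDispersionInflation(m)
    expect_gte(phi, 1)
    p0 <- differentialTest(150L, 80L, 1e5, 1e5)$pvalue
    p1 <- differentialTest(150L, 80L, 1e5, 1e5,
                           dispersionInflation = 3)$pvalue
    expect_gt(p1, p0)
})
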