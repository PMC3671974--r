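# CRE classification, PWM scanning, TATA promoter calls, matched
# background sampling and positional histograms.

randWindow <- function(n = 100L)
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
          collapse = "")

test_that("classifyCre implements the full/half/none hierarchy", {
    pad <- function(x) paste0(strrep("A", 40), x, strrep("A", 40))
    expect_equal(as.character(classifyCre(pad("TGACGTCA"))),
                 "FULL_CRE")
    # one mismatch still counts as a full CRE
    expect_equal(as.character(classifyCre(pad("TGACCTCA"))),
                 "FULL_CRE")
    # a lone reverse half site
    expect_equal(as.character(classifyCre(pad("CGTCA"))), "HALF_CRE")
    expect_equal(as.character(classifyCre(strrep("A", 100))),
                 "NON_CRE")
    # strict forward option drops the reverse pentamer
    expect_equal(as.character(classifyCre(pad("CGTCA"),
                                          strictForwardHalf = TRUE)),
                 "NON_CRE")
    expect_equal(as.character(classifyCre(pad("TGACG"),
                                          strictForwardHalf = TRUE)),
                 "HALF_CRE")
    # windows shorter than the octamer warn and classify NON_CRE
    expect_warning(cls <- classifyCre("TGACGT"), "shorter than 8")
    expect_equal(as.character(cls), "NON_CRE")
    # N never matches
    expect_equal(as.character(classifyCre(pad("TGNCGNCA"))),
                 "NON_CRE")
})

test_that("classifyCre agrees with a string-comparison oracle and is
           strand-symmetric", {
    set.seed(71)
    wins <- replicate(400L, randWindow())
    got <- as.character(classifyCre(wins))
    oracle <- vapply(wins, oracleClassifyCre, character(1),
                     USE.NAMES = FALSE)
    expect_identical(got, oracle)
    # reverse-complement invariance (pattern set closed under RC)
    rc <- vapply(wins, reverseComplementChar, character(1),
                 USE.NAMES = FALSE)
    expect_identical(got, as.character(classifyCre(rc)))
    # FULL precedence: HALF windows contain no distance-1 octamer
    halfWins <- wins[got == "HALF_CRE"]
    if (length(halfWins)) {
        full <- vapply(halfWins, function(w)
            oracleClassifyCre(w) == "FULL_CRE", logical(1))
        expect_false(any(full))
    }
})

test_that("scanPwm scores every offset like the brute-force scorer", {
    counts <- matrix(c(8, 1, 1, 1,  1, 8, 1, 1,  1, 1, 8, 1,
                       1, 1, 1, 8,  4, 4, 4, 4,  1, 8, 1, 1),
                     nrow = 4L,
                     dimnames = list(c("A", "C", "G", "T"), NULL))
    pwm <- newPWM("toy", counts)
    # consensus scores the per-position maxima at offset 0
    cons <- pwmConsensus(pwm)
    hits <- scanPwm(cons, pwm, threshold = pwmMaxScore(pwm) - 1e-9,
                    bothStrands = FALSE)
    expect_equal(hits$start, 1L)
    expect_equal(hits$score, pwmMaxScore(pwm))
    # uniform PWM scores 0 everywhere; no hits above 0
    unif <- newPWM("unif", matrix(5, 4L, 4L,
                                  dimnames = list(c("A", "C", "G",
                                                    "T"), NULL)))
    expect_equal(nrow(scanPwm(randWindow(50L), unif, 0.5)), 0L)
    expect_equal(max(abs(unif@logOdds)), 0)
    # random 2 kb sequence: both strands match the oracle
    set.seed(73)
    s <- randWindow(2000L)
    fwd <- oraclePwmScores(s, counts)
    rcS <- reverseComplementChar(s)
    rcScores <- oraclePwmScores(rcS, counts)
    # a - hit starting at i (forward coords) is a + hit on the RC at
    # position n - w - i + 2
    hits <- scanPwm(s, pwm, threshold = 4)
    for (k in seq_len(nrow(hits))) {
        i <- hits$start[k]
        expected <- if (hits$strand[k] == "+") fwd[i] else
            rcScores[length(rcScores) - i + 1L]
        expect_equal(hits$score[k], expected)
    }
    expect_equal(sum(hits$strand == "+"), sum(fwd >= 4))
    expect_equal(sum(hits$strand == "-"), sum(rcScores >= 4))
    # all-N input yields nothing
    expect_equal(nrow(scanPwm(strrep("N", 100L), pwm, 0)), 0L)
})

test_that("classifyTata flags promoters with a scoring hit near the
           TSS", {
    gi <- smallGenome(200000L)
    tr <- fixtureTranscriptome(gi)
    pwm <- readJasparPwm(system.file("extdata",
                                     "tata_synthetic.jaspar",
                                     package = "ssiCistrome"))
    cons <- pwmConsensus(pwm)
    base <- strrep("A", 200000L)
    put <- function(s, at, motif) {
        substr(s, at, at + nchar(motif) - 1L) <- motif
        s
    }
    # gA TSS at 10,000 (+): consensus planted 30 bp upstream
    seqs <- Biostrings::DNAStringSet(c(chr1 = put(base, 10000L - 30L -
                                                  nchar(cons) + 1L,
                                                  cons)))
    flags <- classifyTata(tr, seqs, pwm)
    expect_true(flags[1])
    expect_false(flags[2])
    # a hit starting exactly 251 bp away is outside the window
    seqs251 <- Biostrings::DNAStringSet(c(chr1 = put(base,
                                                     10000L - 251L,
                                                     cons)))
    expect_false(classifyTata(tr, seqs251, pwm)[1])
    seqs250 <- Biostrings::DNAStringSet(c(chr1 = put(base,
                                                     10000L - 250L,
                                                     cons)))
    expect_true(classifyTata(tr, seqs250, pwm)[1])
})

test_that("sampleMatchedBackground matches the TSS-distance bins and
           is deterministic", {
    study <- smallStudy()
    tr <- study$transcriptome
    gi <- study$genome
    set.seed(79)
    lens <- GenomeInfoDb::seqlengths(gi)
    fg <- GRanges("chr1", IRanges(sample.int(lens[1L] - 1000L, 300L) +
                                  500L, width = 1L), seqinfo = gi)
    bg1 <- sampleMatchedBackground(fg, tr, gi, seed = 3L)
    bg2 <- sampleMatchedBackground(fg, tr, gi, seed = 3L)
    expect_identical(as.data.frame(bg1), as.data.frame(bg2))
    expect_equal(length(bg1), length(fg))
    # bin composition of the background equals the foreground's
    fgBin <- ssiCistrome:::.tssDistanceBin(
        ssiCistrome:::.nearestTssDistance(fg, tr)$distance)
    binLv <- ssiCistrome:::.tssBinUniverse()
    expect_equal(
        as.integer(table(factor(mcols(bg1)$matched_bin, binLv))),
        as.integer(table(factor(fgBin, binLv))))
    # distance distributions agree closely (binned matching)
    bgD <- ssiCistrome:::.nearestTssDistance(bg1, tr)$distance
    fgD <- ssiCistrome:::.nearestTssDistance(fg, tr)$distance
    ks <- suppressWarnings(stats::ks.test(fgD, bgD)$statistic)
    expect_lt(unname(ks), 0.12)
    # degenerate matching: foreground at TSSs -> 0-200 bins only
    tssFg <- GRanges(as.character(seqnames(genes(tr))),
                     IRanges(mcols(genes(tr))$tss, width = 1L),
                     seqinfo = gi)
    bgT <- sampleMatchedBackground(tssFg, tr, gi, seed = 4L)
    expect_true(all(grepl(":0-200$", mcols(bgT)$matched_bin)))
})

test_that("positionalHistogram counts motif offsets per bin", {
    gi <- smallGenome(50000L)
    set.seed(83)
    chars <- sample(c("A", "C", "G"), 50000L, replace = TRUE)
    centers <- seq(2000L, 48000L, by = 2000L)
    offs <- sample(c(-200L, -50L, 0L, 120L), length(centers),
                   replace = TRUE)
    for (i in seq_along(centers)) {
        at <- centers[i] + offs[i]
        chars[at:(at + 7L)] <- strsplit("TGACGTCA", "")[[1L]]
    }
    seqs <- Biostrings::DNAStringSet(c(chr1 = paste(chars,
                                                    collapse = "")))
    pk <- GRanges("chr1", IRanges(centers, width = 1L), seqinfo = gi)
    h <- positionalHistogram(pk, creMatcher(), seqs, flankBp = 300L,
                             binBp = 10L)
    # counting oracle per bin (bins centered on multiples of 10)
    breaks <- seq(-305, 305, by = 10L)
    binOf <- cut(offs, breaks)
    tb <- table(binOf) / length(centers)
    expect_equal(sum(h$frequencies), length(offs) / length(centers))
    got <- h$frequencies[match(names(tb)[tb > 0], levels(binOf))]
    expect_equal(got, as.numeric(tb[tb > 0]))
    # absent motif: all-zero histogram; anchors midway between the
    # planted centers, whose windows contain no T and therefore no
    # octamer within one mismatch of the consensus
    none <- positionalHistogram(
        GRanges("chr1", IRanges(seq(43000L, 47000L, by = 2000L),
                                width = 1L), seqinfo = gi),
        creMatcher(), seqs, flankBp = 300L)
    expect_true(all(none$frequencies == 0))
})

test_that("motifRateByGroup reports rates and Fisher tests vs the
           reference group", {
    gi <- smallGenome(50000L)
    set.seed(89)
    chars <- sample(c("A", "C", "G"), 50000L, replace = TRUE)
    centers <- seq(2000L, 40000L, by = 2000L)   # 20 sites
    groups <- rep(c("INDUCED", "NO_CHANGE"), each = 10L)
    for (i in which(groups == "INDUCED"))
        chars[centers[i]:(centers[i] + 7L)] <-
            strsplit("TGACGTCA", "")[[1L]]
    seqs <- Biostrings::DNAStringSet(c(chr1 = paste(chars,
                                                    collapse = "")))
    sites <- GRanges("chr1", IRanges(centers, width = 1L),
                     seqinfo = gi)
    r <- motifRateByGroup(sites, groups, creMatcher(), seqs)
    expect_equal(r$rate[r$group == "INDUCED"], 1)
    expect_equal(r$rate[r$group == "NO_CHANGE"], 0)
    # forced 10/0 vs 0/10: hypergeometric enumeration oracle
    expect_equal(r$fisher_p[r$group == "INDUCED"],
                 oracleFisherP(10L, 0L, 0L, 10L), tolerance = 1e-9)
    expect_true(is.na(r$fisher_p[r$group == "NO_CHANGE"]))
    # uniform motif content: all rates 1 and p = 1
    r2 <- motifRateByGroup(sites[groups == "INDUCED"],
                           rep(c("A", "NO_CHANGE"), 5L),
                           creMatcher(), seqs)
    expect_equal(r2$rate, c(1, 1))
    expect_equal(r2$fisher_p[r2$group == "A"], 1)
})
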