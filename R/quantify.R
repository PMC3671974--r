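# Consolidation of condition-level peak sets into high-confidence
# regions, per-replicate quantification, and differential-binding tests.

#' Maximum fragment-stack height of a region, in RPM
#'
#' Each tag is extended to `fragmentBp` in its strand direction; the
#' height is the maximum per-base fragment depth inside the region,
#' scaled by 1e6 / library size. Depends only on tags, never on which
#' condition called the region.
#'
#' @param regions `GRanges`.
#' @param lib a [TagLibrary].
#' @param fragmentBp fragment extension length (default 108).
#' @return numeric vector of RPM heights, one per region.
#' @export
regionHeight <- function(regions, lib, fragmentBp = 108L) {
    if (nTags(lib) == 0L) {
        warning("empty library: heights are 0")
        return(rep(0, length(regions)))
    }
    cov <- .fragmentCoverage(lib, fragmentBp, rpm = FALSE)
    out <- numeric(length(regions))
    chr <- as.character(seqnames(regions))
    for (ch in unique(chr)) {
        sel <- which(chr == ch)
        if (!ch %in% names(cov)) { out[sel] <- 0; next }
        v <- Views(cov[[ch]], IRanges(start(regions)[sel],
                                      end(regions)[sel]))
        out[sel] <- viewMaxs(v)
    }
    out * 1e6 / nTags(lib)
}

#' Count tags whose extended fragment overlaps a region
#'
#' Fragment overlap (>= 1 bp), not 5'-end containment, defines
#' membership -- consistent with the height computation.
#'
#' @inheritParams regionHeight
#' @return integer vector of raw counts.
#' @export
countTags <- function(regions, lib, fragmentBp = 108L) {
    frags <- .fragments(lib, fragmentBp)
    countOverlaps(regions, frags, ignore.strand = TRUE)
}

#' Merge two condition-level peak sets into consolidated regions
#'
#' Union-merges overlapping SSI-filtered peaks across the two
#' conditions, quantifies every region in every replicate (height in
#' RPM and raw fragment count), and drops regions whose average height
#' -- the unweighted mean of the two condition means -- is not above
#' `heightThreshold` (default 0.35 RPM). The origin of each surviving
#' region records which call set(s) contributed; heights are computed
#' for all replicates regardless, so a region called in one condition
#' only still carries both conditions' signal. Surviving regions are
#' assigned height quartiles.
#'
#' @param setA,setB SSI-filtered [PeakSet]s for the two conditions.
#' @param libs list of deduplicated per-replicate [TagLibrary]s
#'   covering both conditions.
#' @param heightThreshold average-height cutoff in RPM (default 0.35).
#' @param fragmentBp fragment extension (default 108).
#' @param pseudocountRpm pseudocount for the log2 condition ratio
#'   (default 0.01 RPM).
#' @return a `RangedSummarizedExperiment` with assays `height_rpm` and
#'   `count` (regions x libraries), colData (condition, replicate,
#'   lib_size), and rowData origin, condition means/SEMs, log2_ratio,
#'   avg_height, quartile. Conditions A and B are taken from
#'   `peakSource(setA)` / `peakSource(setB)` ordering.
#' @export
mergeConditionPeaks <- function(setA, setB, libs, heightThreshold = 0.35,
                                fragmentBp = 108L, pseudocountRpm = 0.01) {
    condA <- unique(vapply(libs, condition, character(1)))
    conds <- condA
    if (length(conds) != 2L)
        stop("libs must cover exactly two conditions")
    a <- peaks(setA); b <- peaks(setB)
    un <- reduce(c(.stripRanges(a), .stripRanges(b)), ignore.strand = TRUE)
    un <- sort(un)
    if (!length(un)) {
        warning("empty peak union")
    }
    fromA <- countOverlaps(un, a, ignore.strand = TRUE) > 0L
    fromB <- countOverlaps(un, b, ignore.strand = TRUE) > 0L
    origin <- ifelse(fromA & fromB, "both",
                     ifelse(fromA, paste0(conds[1L], "-only"),
                            paste0(conds[2L], "-only")))
    libCond <- vapply(libs, condition, character(1))
    libRep <- vapply(libs, replicateId, character(1))
    H <- vapply(libs, function(l) regionHeight(un, l, fragmentBp),
                numeric(length(un)))
    C <- vapply(libs, function(l) countTags(un, l, fragmentBp),
                integer(length(un)))
    if (length(un) == 1L) {
        H <- matrix(H, nrow = 1L); C <- matrix(C, nrow = 1L)
    }
    colnames(H) <- colnames(C) <- paste(libCond, libRep, sep = ".")
    selA <- libCond == conds[1L]; selB <- libCond == conds[2L]
    meanA <- rowMeans(H[, selA, drop = FALSE])
    meanB <- rowMeans(H[, selB, drop = FALSE])
    semA <- apply(H[, selA, drop = FALSE], 1L, stats::sd) / sqrt(sum(selA))
    semB <- apply(H[, selB, drop = FALSE], 1L, stats::sd) / sqrt(sum(selB))
    log2Ratio <- log2((meanA + pseudocountRpm) / (meanB + pseudocountRpm))
    avgHeight <- (meanA + meanB) / 2
    keep <- avgHeight > heightThreshold
    un <- un[keep]
    rd <- DataFrame(
        id = sprintf("region_%05d", seq_len(sum(keep))),
        origin = origin[keep], mean_a = meanA[keep], mean_b = meanB[keep],
        sem_a = semA[keep], sem_b = semB[keep],
        log2_ratio = log2Ratio[keep], avg_height = avgHeight[keep])
    rd$quartile <- assignQuartiles(rd$avg_height)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(height_rpm = H[keep, , drop = FALSE],
                      count = C[keep, , drop = FALSE]),
        rowRanges = un,
        colData = DataFrame(condition = libCond, replicate = libRep,
                            lib_size = vapply(libs, nTags, integer(1)),
                            row.names = colnames(H)))
    SummarizedExperiment::rowData(se) <- rd
    S4Vectors::metadata(se) <- list(
        conditionA = conds[1L], conditionB = conds[2L],
        height_threshold = heightThreshold, fragment_bp = fragmentBp,
        pseudocount_rpm = pseudocountRpm,
        sources = c(peakSource(setA), peakSource(setB)))
    se
}

# strand- and mcols-free copy of a GRanges
.stripRanges <- function(gr) GRanges(seqnames(gr),
                                     IRanges(start(gr), end(gr)),
                                     seqinfo = seqinfo(gr))

#' Height quartiles of consolidated regions
#'
#' Quartile 1 holds the lowest heights. Boundaries fall at the
#' 25/50/75 rank percentiles; ties are broken by position in the input
#' (regions arrive in coordinate order), so each quartile size is
#' within 1 of n/4 even under heavy ties.
#'
#' @param avgHeight numeric vector of average heights.
#' @return integer vector of quartile labels 1-4 (all 1 with a warning
#'   when n < 4).
#' @export
assignQuartiles <- function(avgHeight) {
    n <- length(avgHeight)
    if (n < 4L) {
        if (n > 0L) warning("fewer than 4 regions: single stratum")
        return(rep(1L, n))
    }
    ord <- order(avgHeight, seq_len(n))
    rank <- integer(n)
    rank[ord] <- seq_len(n)
    as.integer(ceiling(4 * rank / n))
}

#' Exact binomial differential-binding test for one region
#'
#' Conditional on the total pooled count, tests whether the fasted
#' share of tags matches the fasted share of sequencing depth: an
#' exact two-sided binomial test of x_A out of x_A + x_B against
#' p0 = N_A / (N_A + N_B), two-sided by summing outcome probabilities
#' not exceeding that of the observed outcome. This is a deliberately
#' self-contained stand-in for count-based differential tests; it is
#' anti-conservative under biological overdispersion, which the
#' optional `dispersionInflation` factor (>= 1) mitigates by scaling
#' counts down before testing.
#'
#' @param countsA,countsB per-replicate raw counts for the region.
#' @param libSizesA,libSizesB per-replicate library sizes.
#' @param dispersionInflation variance inflation factor (default 1 =
#'   pure binomial); see [estimateDispersionInflation()].
#' @return list with `pvalue`, `x_a`, `x_b`, `expected_prop`, and
#'   `degenerate` (TRUE when all counts are zero, p = 1).
#' @export
differentialTest <- function(countsA, countsB, libSizesA, libSizesB,
                             dispersionInflation = 1) {
    stopifnot(length(countsA) >= 1L, length(countsB) >= 1L,
              dispersionInflation >= 1)
    xa <- sum(countsA); xb <- sum(countsB)
    p0 <- sum(libSizesA) / (sum(libSizesA) + sum(libSizesB))
    if (xa + xb == 0L)
        return(list(pvalue = 1, x_a = 0L, x_b = 0L, expected_prop = p0,
                    degenerate = TRUE))
    phi <- dispersionInflation
    xaE <- round(xa / phi); nE <- round((xa + xb) / phi)
    xaE <- min(xaE, nE)
    p <- stats::binom.test(xaE, nE, p = p0)$p.value
    list(pvalue = p, x_a = xa, x_b = xb, expected_prop = p0,
         degenerate = FALSE)
}

#' Method-of-moments dispersion inflation factor
#'
#' Median across regions of the ratio of the across-replicate count
#' variance to the Poisson (mean) variance, floored at 1. A crude
#' overdispersion gauge for [differentialTest()].
#'
#' @param countMatrix regions x replicates integer matrix (one
#'   condition).
#' @return numeric(1) inflation factor >= 1.
#' @export
estimateDispersionInflation <- function(countMatrix) {
    mu <- rowMeans(countMatrix)
    v <- apply(countMatrix, 1L, stats::var)
    ok <- mu > 0 & !is.na(v)
    if (!any(ok)) return(1)
    max(1, stats::median(v[ok] / mu[ok]))
}

#' Differential-binding test across all consolidated regions
#'
#' Runs [differentialTest()] per region on the `count` assay, applies
#' [bhAdjust()] and flags regions at the FDR threshold (default 10%).
#'
#' @param se `RangedSummarizedExperiment` from [mergeConditionPeaks()].
#' @param fdr FDR threshold (default 0.10).
#' @param dispersionInflation see [differentialTest()]; `NA` estimates
#'   it from the counts by [estimateDispersionInflation()].
#' @return `DataFrame` with id, pvalue, qvalue, significant.
#' @export
differentialBinding <- function(se, fdr = 0.10, dispersionInflation = 1) {
    cd <- SummarizedExperiment::colData(se)
    condA <- S4Vectors::metadata(se)$conditionA
    selA <- cd$condition == condA
    cnt <- SummarizedExperiment::assay(se, "count")
    if (is.na(dispersionInflation))
        dispersionInflation <- max(
            estimateDispersionInflation(cnt[, selA, drop = FALSE]),
            estimateDispersionInflation(cnt[, !selA, drop = FALSE]))
    p <- vapply(seq_len(nrow(se)), function(i)
        differentialTest(cnt[i, selA], cnt[i, !selA],
                         cd$lib_size[selA], cd$lib_size[!selA],
                         dispersionInflation)$pvalue,
        numeric(1))
    adj <- bhAdjust(p, fdr)
    DataFrame(id = SummarizedExperiment::rowData(se)$id, pvalue = p,
              qvalue = adj$qvalue, significant = adj$significant)
}

#' Benjamini-Hochberg adjustment with significance flags
#'
#' Standard step-up BH via [stats::p.adjust()]; flags are monotone in
#' the p-values.
#'
#' @param pvalues numeric in [0, 1]; NaN/NA are rejected.
#' @param fdr threshold on the adjusted values (default 0.10).
#' @return list with `qvalue` and logical `significant`.
#' @export
bhAdjust <- function(pvalues, fdr = 0.10) {
    if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1))
        stop("p-values must be finite and in [0, 1]")
    q <- stats::p.adjust(pvalues, method = "BH")
    list(qvalue = q, significant = q <= fdr)
}

#' Per-group five-number summaries of heights and log2 ratios
#'
#' @param se `RangedSummarizedExperiment` from [mergeConditionPeaks()].
#' @param groups vector of group labels, one per region.
#' @return data.frame with one row per (group, statistic): n, min, q1,
#'   median, q3, max for `avg_height` and `log2_ratio`. Empty groups
#'   are reported with n = 0 and NA summaries.
#' @export
groupHeightSummary <- function(se, groups) {
    stopifnot(length(groups) == nrow(se))
    rd <- SummarizedExperiment::rowData(se)
    lv <- if (is.factor(groups)) levels(groups) else
        sort(unique(as.character(groups)))
    fivenum_ <- function(x) if (!length(x)) rep(NA_real_, 5L) else
        as.numeric(stats::quantile(x, c(0, .25, .5, .75, 1), type = 7))
    do.call(rbind, lapply(lv, function(g) {
        sel <- which(as.character(groups) == g)
        fh <- fivenum_(rd$avg_height[sel])
        fr <- fivenum_(rd$log2_ratio[sel])
        data.frame(group = g, statistic = c("avg_height", "log2_ratio"),
                   n = length(sel),
                   min = c(fh[1L], fr[1L]), q1 = c(fh[2L], fr[2L]),
                   median = c(fh[3L], fr[3L]), q3 = c(fh[4L], fr[4L]),
                   max = c(fh[5L], fr[5L]))
    }))
}
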