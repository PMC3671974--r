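# Window-based peak caller and the single-sample-independence filter.
# The caller is a pluggable stand-in: ssiFilter() consumes PeakSet
# objects, so BED output of any external caller can be substituted via
# readPeakBed().

#' Caller configuration
#'
#' @param window_bp sliding window width (default 200 bp).
#' @param step_bp window step (default 50 bp).
#' @param fragment_bp tag extension length (default 108 bp, the average
#'   sonication fragment length).
#' @param fdr window-level Benjamini-Hochberg FDR for peak calls
#'   (default 0.05).
#' @param local_bg_bp span of the local background window centered on
#'   each test window (default 10,000 bp).
#' @param min_tags minimum fragments overlapping a window for it to be
#'   tested (default 4).
#' @return a named list, validated.
#' @export
callerConfig <- function(window_bp = 200L, step_bp = 50L,
                         fragment_bp = 108L, fdr = 0.05,
                         local_bg_bp = 10000L, min_tags = 4L) {
    stopifnot(step_bp > 0L, step_bp <= window_bp, fdr > 0, fdr < 1,
              fragment_bp > 0L, local_bg_bp > window_bp, min_tags >= 0L)
    list(window_bp = as.integer(window_bp), step_bp = as.integer(step_bp),
         fragment_bp = as.integer(fragment_bp), fdr = fdr,
         local_bg_bp = as.integer(local_bg_bp),
         min_tags = as.integer(min_tags))
}

#' Call peaks on a pooled tag library
#'
#' Slides windows of `window_bp` every `step_bp` across each
#' chromosome, counts fragments (tags extended to `fragment_bp` in the
#' strand direction) overlapping each window, and tests the count
#' against a Poisson background whose rate is the larger of the global
#' expectation and a local expectation estimated over `local_bg_bp`
#' centered on the window (window excluded). Window p-values are
#' Benjamini-Hochberg adjusted; overlapping significant windows are
#' merged into peaks. The summit is the leftmost position of maximal
#' fragment coverage; `height_rpm` is the maximal coverage scaled by
#' 1e6 / library size. Deterministic: identical inputs and config give
#' identical output.
#'
#' @param pool a [TagLibrary] (typically a condition-level pool).
#' @param genome a `Seqinfo`.
#' @param config a [callerConfig()] list.
#' @param source label for the resulting set.
#' @return a [PeakSet].
#' @export
callPeaks <- function(pool, genome, config = callerConfig(),
                      source = replicateId(pool)) {
    if (length(seqlengths(genome)) == 0L) stop("empty genome")
    if (nTags(pool) == 0L) {
        warning("zero-tag pool: returning an empty PeakSet")
        return(new("PeakSet", peaks = GRanges(seqinfo = genome),
                   source = source, callerConfig = config))
    }
    frags <- .fragments(pool, config$fragment_bp)
    effLen <- config$window_bp + config$fragment_bp - 1L
    genomeLen <- sum(as.numeric(seqlengths(genome)))
    lambdaGlobal <- length(frags) * effLen / genomeLen

    windows <- .tileWindows(genome, config$window_bp, config$step_bp)
    cnt <- countOverlaps(windows, frags, ignore.strand = TRUE)
    test <- which(cnt >= config$min_tags)
    if (!length(test)) {
        return(new("PeakSet", peaks = GRanges(seqinfo = genome),
                   source = source, callerConfig = config))
    }
    tw <- windows[test]
    localWin <- suppressWarnings(resize(tw, config$local_bg_bp,
                                        fix = "center"))
    localWin <- GenomicRanges::trim(localWin)
    localCnt <- countOverlaps(localWin, frags, ignore.strand = TRUE) -
        cnt[test]
    localSpan <- pmax(width(localWin) - config$window_bp, 1L)
    lambdaLocal <- localCnt * effLen / localSpan
    lambda <- pmax(lambdaGlobal, lambdaLocal)
    p <- stats::ppois(cnt[test] - 1L, lambda, lower.tail = FALSE)
    q <- stats::p.adjust(p, method = "BH")
    sig <- q <= config$fdr
    if (!any(sig)) {
        return(new("PeakSet", peaks = GRanges(seqinfo = genome),
                   source = source, callerConfig = config))
    }
    sigWin <- tw[sig]
    merged <- reduce(sigWin, ignore.strand = TRUE)
    merged <- sort(merged)

    # per-peak summit / height from fragment coverage; p/q = best window
    cov <- coverage(frags)
    summit <- integer(length(merged))
    height <- numeric(length(merged))
    for (ch in unique(as.character(seqnames(merged)))) {
        sel <- which(as.character(seqnames(merged)) == ch)
        v <- Views(cov[[ch]], IRanges(start(merged)[sel], end(merged)[sel]))
        summit[sel] <- viewWhichMaxs(v)        # leftmost maximum
        height[sel] <- viewMaxs(v)
    }
    hitP <- findOverlaps(merged, sigWin, ignore.strand = TRUE)
    bestP <- tapply(p[sig][S4Vectors::subjectHits(hitP)],
                    S4Vectors::queryHits(hitP), min)
    bestQ <- tapply(q[sig][S4Vectors::subjectHits(hitP)],
                    S4Vectors::queryHits(hitP), min)
    mcols(merged) <- DataFrame(
        id = sprintf("%s_peak_%05d", source, seq_along(merged)),
        summit = summit,
        height_rpm = height * 1e6 / nTags(pool),
        pvalue = as.numeric(bestP), qvalue = as.numeric(bestQ))
    new("PeakSet", peaks = merged, source = source, callerConfig = config)
}

# tile each chromosome with fixed-width sliding windows
.tileWindows <- function(genome, windowBp, stepBp) {
    chroms <- GenomeInfoDb::seqnames(genome)
    lens <- seqlengths(genome)
    grs <- lapply(chroms, function(ch) {
        len <- lens[[ch]]
        if (len < windowBp) return(GRanges(seqinfo = genome))
        starts <- seq.int(1L, len - windowBp + 1L, by = stepBp)
        GRanges(ch, IRanges(starts, width = windowBp), seqinfo = genome)
    })
    do.call(c, grs)
}

#' Leave-one-out pools of replicate libraries
#'
#' For n replicates, returns the n pools of every combination of n-1
#' replicates, each tagged with the identity of the excluded replicate
#' -- the read subsets on which the SSI test re-calls peaks.
#'
#' @param replicates list of >= 2 [TagLibrary] objects.
#' @return named list of [TagLibrary] pools; names are the excluded
#'   replicate ids.
#' @export
makeLooPools <- function(replicates) {
    if (length(replicates) < 2L)
        stop("the SSI test is undefined for fewer than 2 replicates")
    ids <- vapply(replicates, replicateId, character(1))
    if (anyDuplicated(ids)) stop("replicate ids must be unique")
    pools <- lapply(seq_along(replicates), function(i)
        poolLibraries(replicates[-i],
                      replicateId = sprintf("loo_minus_%s", ids[i])))
    names(pools) <- ids
    pools
}

#' Single-sample-independence (SSI) filter
#'
#' A full-pool peak is retained only if a similar peak is called in
#' EVERY leave-one-out pool; otherwise it is discarded as dependent on
#' a single replicate. "Similar" defaults to >= 1 bp interval overlap;
#' alternatively a maximum summit distance. Two removal tallies are
#' reported per replicate: peaks whose only failing pool excludes that
#' replicate, and peaks counted once per failing pool.
#'
#' @param fullPeaks [PeakSet] called on the all-replicate pool.
#' @param looPeaksets named list of [PeakSet]s, one per leave-one-out
#'   pool (names = excluded replicate ids), produced with the same
#'   caller configuration.
#' @param match "overlap" (default) or "summit".
#' @param maxSummitDist maximum summit distance in bp for
#'   `match = "summit"` (default 200).
#' @return an [SsiResult].
#' @export
ssiFilter <- function(fullPeaks, looPeaksets,
                      match = c("overlap", "summit"),
                      maxSummitDist = 200L) {
    match <- match.arg(match)
    if (!length(looPeaksets)) stop("empty leave-one-out peak set list")
    if (is.null(names(looPeaksets)))
        names(looPeaksets) <- sprintf("replicate%d",
                                      seq_along(looPeaksets))
    cfgs <- lapply(looPeaksets, callerConfigOf)
    same <- vapply(cfgs, identical, logical(1),
                   y = callerConfigOf(fullPeaks))
    if (!all(same))
        warning("leave-one-out sets called with a different configuration")
    full <- peaks(fullPeaks)
    matched <- vapply(looPeaksets, function(ps) {
        .peakMatches(full, peaks(ps), match, maxSummitDist)
    }, logical(length(full)))
    if (length(full) == 1L) matched <- matrix(matched, nrow = 1L,
        dimnames = list(NULL, names(looPeaksets)))
    keep <- if (length(full)) rowSums(!matched) == 0L else logical(0)
    nFail <- if (length(full)) rowSums(!matched) else integer(0)
    removalUnique <- vapply(seq_along(looPeaksets), function(j)
        sum(!matched[, j] & nFail == 1L), integer(1))
    removalPerPool <- vapply(seq_along(looPeaksets), function(j)
        sum(!matched[, j]), integer(1))
    names(removalUnique) <- names(removalPerPool) <- names(looPeaksets)
    ids <- if (!is.null(mcols(full)$id)) mcols(full)$id else
        sprintf("peak_%05d", seq_along(full))
    attributed <- vapply(seq_along(full), function(i) {
        f <- names(looPeaksets)[!matched[i, ]]
        if (!length(f)) "" else paste(f, collapse = ",")
    }, character(1))
    mt <- DataFrame(id = ids, retained = keep, matched)
    mt$attributed_replicates <- attributed
    mkSet <- function(sel, tag) new("PeakSet", peaks = full[sel],
        source = paste0(fullPeaks@source, ":", tag),
        callerConfig = callerConfigOf(fullPeaks))
    new("SsiResult",
        retained = mkSet(keep, "ssi_retained"),
        removed = mkSet(!keep, "ssi_removed"),
        removalUnique = removalUnique, removalPerPool = removalPerPool,
        matchTable = mt)
}

.peakMatches <- function(full, loo, match, maxSummitDist) {
    if (!length(full)) return(logical(0))
    if (!length(loo)) return(rep(FALSE, length(full)))
    if (match == "overlap") {
        countOverlaps(full, loo, ignore.strand = TRUE) > 0L
    } else {
        fs <- mcols(full)$summit
        res <- logical(length(full))
        fullChr <- as.character(seqnames(full))
        looChr <- as.character(seqnames(loo))
        for (ch in unique(fullChr)) {
            sl <- sort(mcols(loo)$summit[looChr == ch])
            fi <- which(fullChr == ch)
            if (!length(sl)) { res[fi] <- FALSE; next }
            lo <- findInterval(fs[fi], sl)
            hi <- pmin(lo + 1L, length(sl))
            lo <- pmax(lo, 1L)
            res[fi] <- pmin(abs(fs[fi] - sl[lo]),
                            abs(fs[fi] - sl[hi])) <= maxSummitDist
        }
        res
    }
}

#' Venn-style comparison of two peak sets
#'
#' Overlap is >= 1 bp. Because the denominator of a two-set overlap
#' percentage is ambiguous, both forms are emitted: the union-based
#' form (merged regions hit by both sets over all merged regions) and
#' per-set fractions.
#'
#' @param setA,setB [PeakSet] objects on the same genome.
#' @return list with `a_only`, `b_only`, `shared` (counts over merged
#'   union regions), `percent_overlap_union`, `frac_a_overlapping`,
#'   `frac_b_overlapping`.
#' @export
comparePeakSets <- function(setA, setB) {
    a <- peaks(setA); b <- peaks(setB)
    un <- reduce(c(GRanges(seqnames(a), IRanges(start(a), end(a))),
                   GRanges(seqnames(b), IRanges(start(b), end(b)))),
                 ignore.strand = TRUE)
    hitA <- countOverlaps(un, a, ignore.strand = TRUE) > 0L
    hitB <- countOverlaps(un, b, ignore.strand = TRUE) > 0L
    shared <- sum(hitA & hitB)
    os <- overlapStats(a, b)
    list(a_only = sum(hitA & !hitB), b_only = sum(hitB & !hitA),
         shared = shared,
         percent_overlap_union = if (length(un))
             100 * shared / length(un) else NA_real_,
         frac_a_overlapping = os$frac_a_overlapping,
         frac_b_overlapping = os$frac_b_overlapping)
}
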