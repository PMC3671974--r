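# CRE classification, PWM scanning, TATA-promoter calling, matched
# background sampling, and positional motif histograms.

CRE_OCTAMER <- "TGACGTCA"
CRE_HALF_SITES <- c("TGACG", "CGTCA")

#' Extract fixed-width sequence windows centered on positions
#'
#' Windows are `widthBp` long, centered on the midpoint of each region
#' (for `widthBp = 100`: 49 bp left of the center base, 50 bp right),
#' clipped at chromosome edges.
#'
#' @param regions `GRanges` (centers are taken as floor((start+end)/2)).
#' @param genomeSeq named `DNAStringSet`.
#' @param widthBp window width (default 100).
#' @return `DNAStringSet`, one window per region.
#' @export
centerWindows <- function(regions, genomeSeq, widthBp = 100L) {
    centers <- floor((start(regions) + end(regions)) / 2)
    chr <- as.character(seqnames(regions))
    lens <- stats::setNames(Biostrings::width(genomeSeq), names(genomeSeq))
    left <- floor((widthBp - 1L) / 2)
    s <- pmax(centers - left, 1L)
    e <- pmin(s + widthBp - 1L, lens[chr])
    s <- pmax(pmin(s, e - widthBp + 1L), 1L)
    out <- Biostrings::DNAStringSet(vapply(seq_along(regions), function(i)
        as.character(Biostrings::subseq(genomeSeq[[chr[i]]], s[i], e[i])),
        character(1)))
    names(out) <- if (!is.null(mcols(regions)$id)) mcols(regions)$id else
        as.character(seq_along(regions))
    out
}

#' Classify sequence windows by CRE content
#'
#' A window is FULL_CRE if it contains any 8-mer within Hamming
#' distance 1 of the palindromic consensus TGACGTCA; otherwise
#' HALF_CRE if it contains an exact pentamer half site (TGACG or, by
#' default, also its reverse complement CGTCA); otherwise NON_CRE.
#' N never matches. Because the pattern set is closed under reverse
#' complement, the classification is strand-symmetric.
#'
#' @param windows `DNAStringSet` (or character vector) of ~100 bp
#'   windows centered on peak centers.
#' @param strictForwardHalf if TRUE only the forward pentamer TGACG
#'   counts as a half site.
#' @return factor with levels FULL_CRE, HALF_CRE, NON_CRE.
#' @export
classifyCre <- function(windows, strictForwardHalf = FALSE) {
    if (is.character(windows))
        windows <- Biostrings::DNAStringSet(windows)
    w <- Biostrings::width(windows)
    short <- w < 8L
    if (any(short))
        warning(sum(short), " window(s) shorter than 8 bp -> NON_CRE")
    full <- rep(FALSE, length(windows))
    ok <- !short
    if (any(ok)) {
        # an octamer must be fully contained in the window: discard
        # the edge-overhanging alignments mismatch-tolerant matching
        # would otherwise report
        hits <- Biostrings::vmatchPattern(CRE_OCTAMER, windows[ok],
                                          max.mismatch = 1,
                                          fixed = TRUE)
        wids <- Biostrings::width(windows[ok])
        full[ok] <- mapply(function(ir, wd)
            length(ir) > 0L && any(BiocGenerics::start(ir) >= 1L &
                                   BiocGenerics::end(ir) <= wd),
            hits, wids, USE.NAMES = FALSE)
    }
    halfPats <- if (strictForwardHalf) CRE_HALF_SITES[1L] else
        CRE_HALF_SITES
    half <- rep(FALSE, length(windows))
    ok5 <- w >= 5L & !short
    if (any(ok5)) {
        for (p in halfPats)
            half[ok5] <- half[ok5] | Biostrings::vcountPattern(
                p, windows[ok5], fixed = TRUE) > 0L
    }
    factor(ifelse(full, "FULL_CRE", ifelse(half, "HALF_CRE", "NON_CRE")),
           levels = c("FULL_CRE", "HALF_CRE", "NON_CRE"))
}

#' Construct a PWM from a count matrix
#'
#' Per-position log-odds are log2 of the pseudocounted base frequency
#' over the background frequency:
#' log2(((c + s) / (total + 4 s)) / q), with per-cell pseudocount
#' s = 0.5 and uniform q = 0.25 by default.
#'
#' @param name motif name.
#' @param counts 4 x width matrix, rows A, C, G, T.
#' @param pseudocount per-cell pseudocount (default 0.5).
#' @param background base frequencies (default uniform).
#' @return a [PWM].
#' @export
newPWM <- function(name, counts, pseudocount = 0.5,
                   background = rep(0.25, 4L)) {
    if (is.null(rownames(counts))) rownames(counts) <- c("A", "C", "G", "T")
    tot <- colSums(counts) + 4 * pseudocount
    p <- sweep(counts + pseudocount, 2L, tot, "/")
    lo <- log2(p / background)
    rownames(lo) <- rownames(counts)
    new("PWM", name = name, counts = counts, logOdds = lo,
        pseudocount = pseudocount, background = background)
}

#' Consensus string of a PWM
#' @param pwm a [PWM].
#' @return character(1).
#' @export
pwmConsensus <- function(pwm) {
    paste(rownames(pwm@counts)[apply(pwm@counts, 2L, which.max)],
          collapse = "")
}

#' Maximum attainable PWM score
#' @param pwm a [PWM].
#' @return numeric(1) sum of per-position maxima of the log-odds.
#' @export
pwmMaxScore <- function(pwm) sum(apply(pwm@logOdds, 2L, max))

# reverse-complemented PWM (reverse positions, swap A<->T, C<->G)
.reverseComplementPwm <- function(pwm) {
    rc <- pwm@counts[c("T", "G", "C", "A"), rev(seq_len(ncol(pwm@counts))),
                     drop = FALSE]
    rownames(rc) <- c("A", "C", "G", "T")
    newPWM(pwm@name, rc, pwm@pseudocount, pwm@background)
}

# per-offset forward-strand log-odds scores of a PWM over a sequence;
# windows containing N score -Inf
.pwmScores <- function(seqChar, pwm) {
    w <- ncol(pwm@logOdds)
    n <- nchar(seqChar)
    if (n < w) return(numeric(0))
    code <- match(strsplit(seqChar, "")[[1L]], c("A", "C", "G", "T"))
    nOff <- n - w + 1L
    sc <- numeric(nOff)
    bad <- logical(nOff)
    for (j in seq_len(w)) {
        b <- code[j:(j + nOff - 1L)]
        miss <- is.na(b)
        bad <- bad | miss
        b[miss] <- 1L
        sc <- sc + pwm@logOdds[cbind(b, j)]
    }
    sc[bad] <- -Inf
    sc
}

#' Scan a sequence with a PWM on both strands
#'
#' Log-odds scoring at every offset; hits with score >= `threshold`
#' are returned sorted by position. Windows containing N are skipped.
#'
#' @param sequence character(1) or `DNAString`.
#' @param pwm a [PWM].
#' @param threshold minimum score.
#' @param bothStrands scan the reverse complement too (default TRUE).
#' @return data.frame with columns start (1-based offset of the
#'   matched window on the given sequence), strand, score, motif.
#' @export
scanPwm <- function(sequence, pwm, threshold, bothStrands = TRUE) {
    seqChar <- toupper(as.character(sequence))
    fwd <- .pwmScores(seqChar, pwm)
    fi <- which(fwd >= threshold)
    hits <- data.frame(start = fi, strand = rep("+", length(fi)),
                       score = fwd[fi])
    if (bothStrands) {
        rcp <- .reverseComplementPwm(pwm)
        rev <- .pwmScores(seqChar, rcp)
        ri <- which(rev >= threshold)
        hits <- rbind(hits,
            data.frame(start = ri, strand = rep("-", length(ri)),
                       score = rev[ri]))
    }
    if (nrow(hits)) {
        hits$motif <- pwm@name
        hits <- hits[order(hits$start, hits$strand), , drop = FALSE]
        rownames(hits) <- NULL
    } else {
        hits$motif <- character(0)
    }
    hits
}

#' TATA-box classification of gene promoters
#'
#' A gene is TATA-containing if the sequence around its TSS carries a
#' PWM hit with score >= `threshold` whose start lies within
#' `windowBp` bp of the TSS (inclusive; a hit starting 251 bp away at
#' the default window is not counted). Windows are truncated at
#' chromosome edges.
#'
#' @param transcriptome a [Transcriptome].
#' @param genomeSeq named `DNAStringSet`.
#' @param pwm TATA [PWM] (see [readJasparPwm()]; the package ships a
#'   consensus-derived synthetic TATA matrix under `inst/extdata`).
#' @param threshold minimum log-odds score (default 6).
#' @param windowBp maximum |hit start - TSS| in bp (default 250).
#' @return logical vector, one flag per transcript.
#' @export
classifyTata <- function(transcriptome, genomeSeq, pwm, threshold = 6,
                         windowBp = 250L) {
    g <- genes(transcriptome)
    tss <- mcols(g)$tss
    chr <- as.character(seqnames(g))
    w <- ncol(pwm@counts)
    lens <- stats::setNames(Biostrings::width(genomeSeq), names(genomeSeq))
    vapply(seq_along(g), function(i) {
        lo <- max(1L, tss[i] - windowBp - w + 1L)
        hi <- min(lens[chr[i]], tss[i] + windowBp + w - 1L)
        s <- as.character(Biostrings::subseq(genomeSeq[[chr[i]]], lo, hi))
        hits <- scanPwm(s, pwm, threshold)
        if (!nrow(hits)) return(FALSE)
        any(abs(hits$start + lo - 1L - tss[i]) <= windowBp)
    }, logical(1))
}

# signed-TSS-distance bin labels used for matched background sampling;
# breakpoints mirror the annotation windows used elsewhere (200 bp,
# 2 kb, 10 kb, 50 kb per side)
.tssDistanceBin <- function(d) {
    mag <- cut(abs(d), c(-1, 200, 2000, 10000, 50000, Inf),
               labels = c("0-200", "200-2k", "2k-10k", "10k-50k", ">50k"))
    side <- ifelse(d < 0, "up", "down")
    paste0(side, ":", as.character(mag))
}

# order over bins for the nearest-non-empty fallback
.tssBinUniverse <- function() {
    mags <- c("0-200", "200-2k", "2k-10k", "10k-50k", ">50k")
    c(paste0("up:", mags), paste0("down:", mags))
}

#' Sample background positions matched on TSS distance
#'
#' For each foreground site, draws `nPerSite` genomic positions whose
#' signed nearest-TSS distance falls in the same distance bin
#' (log-spaced per-side bins at 200 bp / 2 kb / 10 kb / 50 kb),
#' excluding the foreground intervals themselves. Deterministic under
#' the seed. Bins with no sampled candidates fall back to the nearest
#' non-empty bin with a warning.
#'
#' @param foreground `GRanges` of foreground sites.
#' @param transcriptome a [Transcriptome].
#' @param genome a `Seqinfo`.
#' @param nPerSite background positions per foreground site (default 1).
#' @param seed integer seed.
#' @param oversample candidate pool size multiplier (default 200).
#' @return width-1 `GRanges` of background positions with mcols
#'   `matched_bin`.
#' @export
sampleMatchedBackground <- function(foreground, transcriptome, genome,
                                    nPerSite = 1L, seed = 1L,
                                    oversample = 200L) {
    stopifnot(length(foreground) > 0L)
    set.seed(seed)
    centers <- GRanges(seqnames(foreground),
                       IRanges(floor((start(foreground) +
                                      end(foreground)) / 2), width = 1L),
                       seqinfo = genome)
    fgBin <- .tssDistanceBin(.nearestTssDistance(centers,
                                                 transcriptome)$distance)
    need <- table(factor(fgBin, levels = .tssBinUniverse())) * nPerSite

    # candidate pool: uniform positions, binned the same way
    lens <- seqlengths(genome)
    nCand <- oversample * length(foreground) * nPerSite
    chrIdx <- sample.int(length(lens), nCand, replace = TRUE,
                         prob = lens / sum(lens))
    pos <- floor(stats::runif(nCand) * lens[chrIdx]) + 1L
    cand <- GRanges(names(lens)[chrIdx], IRanges(pos, width = 1L),
                    seqinfo = genome)
    cand <- cand[countOverlaps(cand, foreground,
                               ignore.strand = TRUE) == 0L]
    candBin <- .tssDistanceBin(.nearestTssDistance(cand,
                                                   transcriptome)$distance)

    binOrder <- .tssBinUniverse()
    out <- GRanges(seqinfo = genome)
    outBins <- character(0)
    for (b in names(need)) {
        k <- need[[b]]
        if (k == 0L) next
        pool <- which(candBin == b)
        if (!length(pool)) {
            warning("no background candidates in bin ", b,
                    "; falling back to nearest non-empty bin")
            bi <- match(b, binOrder)
            others <- order(abs(seq_along(binOrder) - bi))
            for (j in others) {
                pool <- which(candBin == binOrder[j])
                if (length(pool)) break
            }
        }
        take <- pool[sample.int(length(pool), k, replace =
                                length(pool) < k)]
        out <- c(out, cand[take])
        outBins <- c(outBins, rep(b, k))
    }
    mcols(out)$matched_bin <- outBins
    sort(out, ignore.strand = TRUE)
}

#' Motif matchers for positional histograms and group rates
#'
#' `creMatcher()` reports start offsets of full-CRE octamer matches
#' (Hamming distance <= 1); `halfCreMatcher()` exact pentamer matches;
#' `pwmMatcher(pwm, threshold)` PWM hits on both strands.
#'
#' @return a function(DNAStringSet) -> list of integer offset vectors.
#' @export
creMatcher <- function() {
    function(windows) {
        lapply(seq_along(windows), function(i) {
            m <- Biostrings::matchPattern(CRE_OCTAMER, windows[[i]],
                                          max.mismatch = 1,
                                          fixed = TRUE)
            s <- Biostrings::start(m)
            s[s >= 1L & Biostrings::end(m) <=
                  length(windows[[i]])]
        })
    }
}

#' @rdname creMatcher
#' @param strictForward only the forward pentamer (default FALSE).
#' @export
halfCreMatcher <- function(strictForward = FALSE) {
    pats <- if (strictForward) CRE_HALF_SITES[1L] else CRE_HALF_SITES
    function(windows) {
        lapply(seq_along(windows), function(i) {
            sort(unique(unlist(lapply(pats, function(p)
                Biostrings::start(Biostrings::matchPattern(
                    p, windows[[i]], fixed = TRUE))))))
        })
    }
}

#' @rdname creMatcher
#' @param pwm a [PWM].
#' @param threshold minimum log-odds score.
#' @export
pwmMatcher <- function(pwm, threshold) {
    function(windows) {
        lapply(seq_along(windows), function(i)
            scanPwm(as.character(windows[[i]]), pwm, threshold)$start)
    }
}

#' Positional histogram of motif occurrences around peak centers
#'
#' Motif occurrence frequency per offset bin relative to peak centers,
#' averaged over peaks (occurrences per peak per bin). Offsets are
#' measured from the peak center to the motif match start.
#'
#' @param peaksGr `GRanges` of peaks (centers used as anchors).
#' @param matcher a matcher from [creMatcher()] and friends.
#' @param genomeSeq named `DNAStringSet`.
#' @param flankBp half-width of the window around each center
#'   (default 500).
#' @param binBp bin resolution (default 10).
#' @return list with `bin_centers`, `frequencies`, `bin_bp`, `n_peaks`.
#' @export
positionalHistogram <- function(peaksGr, matcher, genomeSeq,
                                flankBp = 500L, binBp = 10L) {
    widthBp <- 2L * flankBp + 1L
    win <- centerWindows(peaksGr, genomeSeq, widthBp)
    offs <- matcher(win)
    # bins centered on multiples of binBp, with a bin centered at 0
    breaks <- seq(-flankBp - binBp / 2, flankBp + binBp / 2,
                  by = binBp)
    centersOfBins <- seq(-flankBp, flankBp, by = binBp)
    rel <- unlist(offs) - (flankBp + 1L)   # match start relative to center
    rel <- rel[rel >= -flankBp & rel <= flankBp]
    counts <- if (length(rel))
        as.numeric(table(cut(rel, breaks))) else
        numeric(length(centersOfBins))
    list(bin_centers = centersOfBins,
         frequencies = counts / length(peaksGr),
         bin_bp = binBp, n_peaks = length(peaksGr))
}

#' Motif occurrence rates per site group with Fisher tests
#'
#' Fraction of sites in each group with at least one motif match
#' within +/- `windowBp` of the site center, and a two-sided Fisher
#' exact p-value of each group against the reference group.
#'
#' @param sites `GRanges` of site regions.
#' @param groups vector of group labels, one per site.
#' @param matcher a matcher function.
#' @param genomeSeq named `DNAStringSet`.
#' @param windowBp half-window around centers (default 250).
#' @param reference reference group label (default "NO_CHANGE").
#' @return data.frame with group, n, n_with_motif, rate, fisher_p
#'   (NA for the reference itself and for empty groups).
#' @export
motifRateByGroup <- function(sites, groups, matcher, genomeSeq,
                             windowBp = 250L, reference = "NO_CHANGE") {
    stopifnot(length(groups) == length(sites))
    win <- centerWindows(sites, genomeSeq, 2L * windowBp + 1L)
    hasMotif <- lengths(matcher(win)) > 0L
    lv <- if (is.factor(groups)) levels(groups) else
        unique(as.character(groups))
    groups <- as.character(groups)
    refSel <- groups == reference
    out <- do.call(rbind, lapply(lv, function(g) {
        sel <- groups == g
        n <- sum(sel)
        hit <- sum(hasMotif[sel])
        p <- if (g == reference || n == 0L || !any(refSel)) NA_real_ else
            stats::fisher.test(matrix(c(hit, n - hit,
                                        sum(hasMotif[refSel]),
                                        sum(refSel) - sum(hasMotif[refSel])),
                                      nrow = 2L))$p.value
        data.frame(group = g, n = n, n_with_motif = hit,
                   rate = if (n) hit / n else NA_real_, fisher_p = p)
    }))
    rownames(out) <- NULL
    out
}
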