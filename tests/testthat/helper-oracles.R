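# Independent brute-force oracles and fixture builders. Everything in
# this file deliberately avoids the package's own code paths (plain R
# arithmetic and loops only), so each oracle is an independent route
# to the same answer.

suppressPackageStartupMessages({
    library(GenomicRanges)
    library(Biostrings)
})

smallGenome <- function(len = 10000L, nChrom = 1L) {
    genomeIndex(stats::setNames(rep(len, nChrom),
                                sprintf("chr%d", seq_len(nChrom))))
}

# random width-1 stranded tag GRanges on a genome
randomTags <- function(n, genome) {
    lens <- GenomeInfoDb::seqlengths(genome)
    ch <- sample(names(lens), n, replace = TRUE)
    GRanges(ch, IRanges(sapply(ch, function(c)
        sample.int(lens[[c]], 1L)), width = 1L),
        strand = sample(c("+", "-"), n, replace = TRUE),
        seqinfo = genome)
}

# data.frame view of a tag GRanges (for multiset comparisons)
tagDf <- function(gr) {
    d <- data.frame(chrom = as.character(seqnames(gr)),
                    pos = start(gr),
                    strand = as.character(strand(gr)))
    d[order(d$chrom, d$pos, d$strand), , drop = FALSE]
}

# per-base fragment depth over one chromosome, by explicit looping
oraclePileup <- function(tagDf, fragment, chromLen) {
    depth <- numeric(chromLen)
    for (i in seq_len(nrow(tagDf))) {
        p <- tagDf$pos[i]
        if (tagDf$strand[i] == "+") {
            s <- p; e <- min(p + fragment - 1L, chromLen)
        } else {
            s <- max(p - fragment + 1L, 1L); e <- p
        }
        depth[s:e] <- depth[s:e] + 1
    }
    depth
}

# number of tags whose extended fragment overlaps [s, e]
oracleFragmentCount <- function(tagDf, fragment, s, e, chromLen) {
    n <- 0L
    for (i in seq_len(nrow(tagDf))) {
        p <- tagDf$pos[i]
        if (tagDf$strand[i] == "+") {
            fs <- p; fe <- min(p + fragment - 1L, chromLen)
        } else {
            fs <- max(p - fragment + 1L, 1L); fe <- p
        }
        if (fs <= e && fe >= s) n <- n + 1L
    }
    n
}

# step-up Benjamini-Hochberg, written from the definition
oracleBH <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- numeric(m)
    prev <- 1
    for (i in m:1) {
        val <- min(prev, p[o[i]] * m / i)
        q[o[i]] <- val
        prev <- val
    }
    q
}

# two-sided Fisher p-value by full hypergeometric enumeration
oracleFisherP <- function(a, b, c, d) {
    r1 <- a + b; c1 <- a + c; n <- a + b + c + d
    lo <- max(0L, c1 - (n - r1)); hi <- min(r1, c1)
    probs <- vapply(lo:hi, function(x)
        exp(lchoose(r1, x) + lchoose(n - r1, c1 - x) - lchoose(n, c1)),
        numeric(1))
    pObs <- probs[a - lo + 1L]
    sum(probs[probs <= pObs * (1 + 1e-7)])
}

# CRE classification by explicit string comparison
oracleClassifyCre <- function(seqChar) {
    hamming <- function(x, y)
        sum(strsplit(x, "")[[1L]] != strsplit(y, "")[[1L]])
    n <- nchar(seqChar)
    if (n >= 8L) for (i in 1:(n - 7L)) {
        k <- substr(seqChar, i, i + 7L)
        if (!grepl("N", k) && hamming(k, "TGACGTCA") <= 1L)
            return("FULL_CRE")
        if (grepl("N", k)) {
            # an N never matches: positions with N count as mismatches
            if (hamming(k, "TGACGTCA") <= 1L) return("FULL_CRE")
        }
    }
    if (grepl("TGACG", seqChar, fixed = TRUE) ||
        grepl("CGTCA", seqChar, fixed = TRUE)) return("HALF_CRE")
    "NON_CRE"
}

# per-offset PWM log-odds by explicit looping (forward strand)
oraclePwmScores <- function(seqChar, counts, pseudo = 0.5, bg = 0.25) {
    w <- ncol(counts)
    lo <- log2(sweep(counts + pseudo, 2L,
                     colSums(counts) + 4 * pseudo, "/") / bg)
    chars <- strsplit(seqChar, "")[[1L]]
    n <- length(chars)
    if (n < w) return(numeric(0))
    vapply(1:(n - w + 1L), function(i) {
        s <- 0
        for (j in 1:w) {
            b <- chars[i + j - 1L]
            if (!b %in% c("A", "C", "G", "T")) return(-Inf)
            s <- s + lo[b, j]
        }
        s
    }, numeric(1))
}

reverseComplementChar <- function(x) {
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    paste(rev(comp[strsplit(x, "")[[1L]]]), collapse = "")
}

# random disjoint peak set on one chromosome, as a PeakSet
randomPeakSet <- function(nMax, genome, source = "x",
                          chromLen = GenomeInfoDb::seqlengths(genome)[1L]) {
    n <- sample.int(nMax, 1L)
    starts <- sort(sample.int(chromLen - 400L, n))
    widths <- sample(50:200, n, replace = TRUE)
    ends <- pmin(starts + widths, chromLen)
    keep <- c(TRUE, diff(starts) > 250L)   # enforce disjoint
    starts <- starts[keep]; ends <- ends[keep]
    gr <- GRanges("chr1", IRanges(starts, ends), seqinfo = genome)
    mcols(gr) <- S4Vectors::DataFrame(
        id = sprintf("%s_%03d", source, seq_along(gr)),
        summit = as.integer(floor((starts + ends) / 2)),
        height_rpm = runif(length(gr), 0.1, 5),
        pvalue = runif(length(gr)), qvalue = runif(length(gr)))
    new("PeakSet", peaks = gr, source = source,
        callerConfig = callerConfig())
}

# tiny hand-built transcriptome: plus- and minus-strand coding genes
# with generous first exons (long 5'UTRs) for feature classification
fixtureTranscriptome <- function(genome = smallGenome(200000L)) {
    d <- data.frame(
        gene = c("gA", "gB"), tx = c("txA", "txB"),
        chrom = "chr1", strand = c("+", "-"),
        txStart = c(9999L, 59999L), txEnd = c(15000L, 65000L),
        cdsStart = c(10500L, 60300L), cdsEnd = c(14700L, 64400L),
        exonCount = c(3L, 3L),
        exonStarts = c("9999,11999,13999,", "59999,61999,63999,"),
        exonEnds = c("11000,13000,15000,", "61000,63000,65000,"),
        stringsAsFactors = FALSE)
    transcriptomeFromTable(d, genome)
}

# deterministic small tag library from explicit positions
libFromPositions <- function(pos, strand, genome, chrom = "chr1",
                             id = "lib", cond = "c", dedupe = FALSE) {
    gr <- GRanges(chrom, IRanges(pos, width = 1L), strand = strand,
                  seqinfo = genome)
    if (dedupe) dedupeTags(gr, genome, id, cond) else
        new("TagLibrary", tags = sort(gr, ignore.strand = TRUE),
            replicateId = id, condition = cond, deduplicated = FALSE)
}
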