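# Core genomic data model: tag libraries and elementary interval ops.
# All in-memory coordinates follow the GRanges convention (1-based,
# closed); BED-family files are shifted at the I/O boundary.

#' Build a genome index from chromosome lengths
#'
#' @param chromLengths named integer vector of chromosome lengths (bp).
#' @return a [GenomeInfoDb::Seqinfo] used to bound-check every
#'   coordinate in the system.
#' @examples
#' gi <- genomeIndex(c(chr1 = 1e6, chr2 = 5e5))
#' @export
genomeIndex <- function(chromLengths) {
    if (is.null(names(chromLengths)) || anyDuplicated(names(chromLengths)))
        stop("chromosome names must be present and unique")
    if (any(chromLengths <= 0)) stop("chromosome lengths must be positive")
    Seqinfo(seqnames = names(chromLengths),
            seqlengths = as.integer(chromLengths))
}

#' Deduplicate raw tags into a TagLibrary
#'
#' Redundant reads -- tags sharing (chromosome, 5'-end position,
#' strand) -- are collapsed to a single tag, the standard pre-pooling
#' step for single-end ChIP libraries. Input order is irrelevant.
#'
#' @param rawTags width-1 stranded `GRanges` of 5'-end positions.
#' @param genome a `Seqinfo`; tags outside its bounds are an error that
#'   names the offending record.
#' @param replicateId,condition labels stored on the library.
#' @return a [TagLibrary] with one tag per distinct triple.
#' @examples
#' gi <- genomeIndex(c(chr1 = 1000))
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(100, 100), width = 1),
#'                              strand = c("+", "+"))
#' nTags(dedupeTags(gr, gi, "rep1", "fasted"))  # 1
#' @export
dedupeTags <- function(rawTags, genome, replicateId = "lib",
                       condition = "cond") {
    gr <- .coerceTags(rawTags, genome)
    gr <- unique(gr)
    gr <- sort(gr, ignore.strand = TRUE)
    new("TagLibrary", tags = gr, replicateId = as.character(replicateId),
        condition = as.character(condition), deduplicated = TRUE)
}

# normalize a tag GRanges onto a genome index, bound-checking coordinates
.coerceTags <- function(gr, genome) {
    if (!is(gr, "GRanges")) stop("tags must be a GRanges")
    if (length(gr) && any(width(gr) != 1L))
        stop("tags must be width-1 (5'-end positions)")
    bad <- !(as.character(GenomeInfoDb::seqnames(gr)) %in%
             GenomeInfoDb::seqnames(genome))
    if (any(bad))
        stop(sprintf("tag %d on unknown chromosome '%s'",
                     which(bad)[1L],
                     as.character(seqnames(gr))[which(bad)[1L]]))
    # bound violations are reported below with the offending record
    gr <- suppressWarnings(GRanges(as.character(seqnames(gr)),
                                   IRanges(start(gr), width = 1L),
                                   strand = strand(gr),
                                   seqinfo = genome))
    lens <- seqlengths(genome)[as.character(seqnames(gr))]
    bad <- which(start(gr) < 1L | start(gr) > lens)
    if (length(bad))
        stop(sprintf("tag %d (%s:%d) outside chromosome bounds", bad[1L],
                     as.character(seqnames(gr))[bad[1L]], start(gr)[bad[1L]]))
    gr
}

#' Pool tag libraries into a single read set
#'
#' Multiset union: no cross-replicate deduplication is performed, so
#' `nTags` of the pool is the sum over inputs, mirroring the pooling of
#' non-redundant per-replicate read sets into one condition-level set.
#'
#' @param libs list of [TagLibrary] objects on the same genome.
#' @param replicateId,condition labels for the pool; defaults derive
#'   from the inputs.
#' @return a [TagLibrary] (flagged as not deduplicated).
#' @export
poolLibraries <- function(libs, replicateId = NULL, condition = NULL) {
    stopifnot(length(libs) >= 1L)
    lapply(libs, function(l) if (!is(l, "TagLibrary"))
        stop("all inputs must be TagLibrary objects"))
    sis <- lapply(libs, function(l) seqinfo(tags(l)))
    if (!all(vapply(sis[-1], identical, logical(1), y = sis[[1L]])))
        stop("libraries come from different genome indexes")
    conds <- unique(vapply(libs, condition, character(1)))
    if (is.null(condition)) {
        if (length(conds) > 1L)
            warning("pooling libraries from mixed conditions: ",
                    paste(conds, collapse = ","))
        condition <- paste(conds, collapse = "+")
    }
    if (is.null(replicateId))
        replicateId <- paste0("pool(",
            paste(vapply(libs, replicateId, character(1)), collapse = ","), ")")
    gr <- sort(do.call(c, lapply(libs, tags)), ignore.strand = TRUE)
    new("TagLibrary", tags = gr, replicateId = replicateId,
        condition = condition, deduplicated = length(libs) == 1L &&
            libs[[1L]]@deduplicated)
}

#' Merge intervals into a minimal disjoint sorted set
#'
#' Thin strand-blind wrapper around [GenomicRanges::reduce()]: the
#' output covers exactly the same bases as the input union.
#'
#' @param intervals a `GRanges`.
#' @return sorted, disjoint `GRanges`.
#' @export
mergeIntervals <- function(intervals) {
    stopifnot(is(intervals, "GRanges"))
    sort(reduce(intervals, ignore.strand = TRUE))
}

#' Overlap summary between two interval sets
#'
#' An interval of `setA` counts as shared when it overlaps at least
#' `minOverlap` bp of any interval in `setB` (and symmetrically for
#' `setB`).
#'
#' @param setA,setB `GRanges` on the same genome.
#' @param minOverlap minimum overlap in bp to count as shared (default 1).
#' @return list with counts `a_only`, `b_only`, `shared_a`, `shared_b`
#'   and fractions `frac_a_overlapping`, `frac_b_overlapping`.
#' @export
overlapStats <- function(setA, setB, minOverlap = 1L) {
    sharedA <- sum(countOverlaps(setA, setB, minoverlap = minOverlap,
                                 ignore.strand = TRUE) > 0L)
    sharedB <- sum(countOverlaps(setB, setA, minoverlap = minOverlap,
                                 ignore.strand = TRUE) > 0L)
    list(a_only = length(setA) - sharedA,
         b_only = length(setB) - sharedB,
         shared_a = sharedA, shared_b = sharedB,
         frac_a_overlapping = if (length(setA)) sharedA / length(setA) else NA_real_,
         frac_b_overlapping = if (length(setB)) sharedB / length(setB) else NA_real_)
}

# ---- fragment / pileup helpers shared by caller and quantification ----

# extend width-1 5'-end tags to fragments of the given length in the
# strand direction, clipped to chromosome bounds
.fragments <- function(lib, fragmentBp) {
    stopifnot(fragmentBp > 0L)
    gr <- tags(lib)
    if (!length(gr)) return(gr)
    fr <- suppressWarnings(resize(gr, width = fragmentBp, fix = "start"))
    GenomicRanges::trim(fr)
}

# RPM-scaled fragment coverage as an RleList
.fragmentCoverage <- function(lib, fragmentBp, rpm = TRUE) {
    fr <- .fragments(lib, fragmentBp)
    cov <- coverage(fr)
    if (rpm && nTags(lib) > 0L) cov <- cov * (1e6 / nTags(lib))
    cov
}

# signed strand-relative distance from each query position to its
# nearest TSS (negative = upstream of the gene's direction); ties
# between equidistant TSSs break toward the gene earlier in coordinate
# order. Deterministic by construction.
.nearestTssDistance <- function(positions, transcriptome) {
    g <- genes(transcriptome)
    tssPos <- mcols(g)$tss
    tssChr <- as.character(seqnames(g))
    tssStr <- as.character(strand(g))
    qChr <- as.character(seqnames(positions))
    qPos <- start(positions)
    out <- rep(NA_real_, length(positions))
    idx <- rep(NA_integer_, length(positions))
    for (ch in unique(qChr)) {
        sel <- which(tssChr == ch)
        qi <- which(qChr == ch)
        if (!length(sel)) next
        ord <- sel[order(tssPos[sel], sel)]
        tp <- tssPos[ord]
        lo <- findInterval(qPos[qi], tp)
        hi <- pmin(lo + 1L, length(tp))
        lo <- pmax(lo, 1L)
        dLo <- abs(qPos[qi] - tp[lo])
        dHi <- abs(qPos[qi] - tp[hi])
        pick <- ifelse(dHi < dLo, hi, lo)  # tie -> lo (earlier coordinate)
        gi <- ord[pick]
        d <- qPos[qi] - tssPos[gi]
        d <- ifelse(tssStr[gi] == "-", -d, d)
        out[qi] <- d
        idx[qi] <- gi
    }
    list(distance = out, gene = idx)
}
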