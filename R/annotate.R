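# Genomic feature classification, target-gene mapping, regulation
# groups, enrichment statistics, and co-localization profiles.

FEATURE_LEVELS <- c("PROMOTER", "FIVE_UTR", "EXON_CDS", "THREE_UTR",
                    "INTRON", "INTERGENIC")
REGULATION_LEVELS <- c("INDUCED", "REPRESSED", "NO_CHANGE", "UNASSIGNED")

# strand-relative promoter windows: TSS - upstream .. TSS + downstream
.promoterWindows <- function(transcriptome, upstream = 2000L,
                             downstream = 200L) {
    g <- genes(transcriptome)
    tss <- GRanges(seqnames(g), IRanges(mcols(g)$tss, width = 1L),
                   strand = strand(g), seqinfo = seqinfo(g))
    GenomicRanges::trim(suppressWarnings(
        promoters(tss, upstream = upstream, downstream = downstream + 1L)))
}

# decompose a transcriptome into feature GRanges for classification
.featureRegions <- function(transcriptome) {
    g <- genes(transcriptome)
    ex <- exonsOf(transcriptome)
    m <- mcols(g)
    cds5 <- ifelse(is.na(m$cds_start), NA_integer_,
                   pmin(m$cds_start, m$cds_end))
    cds3 <- ifelse(is.na(m$cds_start), NA_integer_,
                   pmax(m$cds_start, m$cds_end))
    minus <- as.character(strand(g)) == "-"
    acc <- list(five_utr = list(), three_utr = list(),
                cds_exon = list(), intron = list(),
                first_intron = list())
    lvls <- seqlevels(seqinfo(g))
    chrV <- factor(as.character(seqnames(g)), levels = lvls)
    for (i in seq_along(g)) {
        e <- ex[[i]]
        ch <- chrV[i]
        if (length(e) > 1L) {
            gs <- end(e)[-length(e)] + 1L
            ge <- start(e)[-1L] - 1L
            ok <- ge >= gs
            if (any(ok)) {
                gaps <- IRanges(gs[ok], ge[ok])
                acc$intron[[i]] <- GRanges(ch, gaps)
                acc$first_intron[[i]] <- GRanges(ch,
                    gaps[if (minus[i]) length(gaps) else 1L])
            }
        }
        if (!is.na(cds5[i])) {
            er <- IRanges(start(e), end(e))
            cdsI <- IRanges::intersect(er, IRanges(cds5[i], cds3[i]))
            upUtr <- IRanges::setdiff(er, IRanges(cds5[i], end(g)[i]))
            dnUtr <- IRanges::setdiff(er, IRanges(start(g)[i], cds3[i]))
            acc$cds_exon[[i]] <- GRanges(ch, cdsI)
            # upstream-in-coordinates UTR is 5' on +, 3' on -
            if (minus[i]) {
                acc$five_utr[[i]] <- GRanges(ch, dnUtr)
                acc$three_utr[[i]] <- GRanges(ch, upUtr)
            } else {
                acc$five_utr[[i]] <- GRanges(ch, upUtr)
                acc$three_utr[[i]] <- GRanges(ch, dnUtr)
            }
        }
    }
    bind <- function(xs) {
        xs <- xs[!vapply(xs, is.null, logical(1))]
        if (!length(xs)) return(GRanges(seqinfo = seqinfo(g)))
        out <- do.call(c, unname(xs))
        seqlevels(out) <- seqlevels(seqinfo(g))
        seqinfo(out) <- seqinfo(g)
        out
    }
    list(promoter = .promoterWindows(transcriptome),
         five_utr = bind(acc$five_utr), cds_exon = bind(acc$cds_exon),
         three_utr = bind(acc$three_utr), intron = bind(acc$intron),
         first_intron = bind(acc$first_intron))
}

#' Classify site centers against gene architecture
#'
#' The exact center of each region is compared to the transcriptome.
#' Default priority: PROMOTER (2 kb upstream to 200 bp downstream of
#' any TSS, strand-relative) > FIVE_UTR (5'UTR bases beyond +200 bp) >
#' EXON_CDS > THREE_UTR > INTRON; anything else is INTERGENIC.
#' `mode = "literal"` ranks INTRON above the exonic classes instead.
#' `first_intron` flags centers inside intron 1 of any transcript;
#' `within_50kb_tss` flags intergenic centers within 50 kb of a TSS.
#'
#' @param sites `GRanges` of regions (centers are used).
#' @param transcriptome a [Transcriptome].
#' @param mode "default" or "literal" feature priority.
#' @return `DataFrame` with `feature` (factor), `first_intron`,
#'   `within_50kb_tss`, `tss_distance` (signed, strand-relative).
#' @export
classifySite <- function(sites, transcriptome,
                         mode = c("default", "literal")) {
    mode <- match.arg(mode)
    centers <- GRanges(seqnames(sites),
                       IRanges(floor((start(sites) + end(sites)) / 2),
                               width = 1L),
                       seqinfo = seqinfo(sites))
    fr <- .featureRegions(transcriptome)
    hit <- function(set) countOverlaps(centers, set,
                                       ignore.strand = TRUE) > 0L
    inProm <- hit(fr$promoter)
    in5 <- hit(fr$five_utr)
    inCds <- hit(fr$cds_exon)
    in3 <- hit(fr$three_utr)
    inIntron <- hit(fr$intron)
    inFirst <- hit(fr$first_intron)
    priority <- if (mode == "default")
        list(PROMOTER = inProm, FIVE_UTR = in5, EXON_CDS = inCds,
             THREE_UTR = in3, INTRON = inIntron)
    else
        list(PROMOTER = inProm, INTRON = inIntron, EXON_CDS = inCds,
             FIVE_UTR = in5, THREE_UTR = in3)
    feature <- rep("INTERGENIC", length(centers))
    for (nm in rev(names(priority))) feature[priority[[nm]]] <- nm
    d <- .nearestTssDistance(centers, transcriptome)$distance
    DataFrame(feature = factor(feature, levels = FEATURE_LEVELS),
              first_intron = inFirst & feature == "INTRON",
              within_50kb_tss = feature == "INTERGENIC" &
                  !is.na(d) & abs(d) <= 50000,
              tss_distance = d)
}

#' Regulatory-context site classifier
#'
#' An alternative, independent scheme: PROXIMAL (-2 kb..+200 bp of a
#' TSS), DISTAL (-10 kb..-2 kb upstream), INTRONIC, EXONIC, OTHER.
#'
#' @inheritParams classifySite
#' @return factor per site.
#' @export
classifySiteRegulatory <- function(sites, transcriptome) {
    centers <- GRanges(seqnames(sites),
                       IRanges(floor((start(sites) + end(sites)) / 2),
                               width = 1L),
                       seqinfo = seqinfo(sites))
    fr <- .featureRegions(transcriptome)
    g <- genes(transcriptome)
    tss <- GRanges(seqnames(g), IRanges(mcols(g)$tss, width = 1L),
                   strand = strand(g), seqinfo = seqinfo(g))
    prox <- GenomicRanges::trim(suppressWarnings(
        promoters(tss, 2000L, 201L)))
    distal <- GenomicRanges::trim(suppressWarnings(
        promoters(tss, 10000L, 0L)))
    hit <- function(set) countOverlaps(centers, set,
                                       ignore.strand = TRUE) > 0L
    exonic <- countOverlaps(centers, unlist(exonsOf(transcriptome)),
                            ignore.strand = TRUE) > 0L
    cls <- rep("OTHER", length(centers))
    cls[exonic] <- "EXONIC"
    cls[hit(fr$intron)] <- "INTRONIC"
    cls[hit(distal)] <- "DISTAL"
    cls[hit(prox)] <- "PROXIMAL"
    factor(cls, levels = c("PROXIMAL", "DISTAL", "INTRONIC", "EXONIC",
                           "OTHER"))
}

#' Histogram of signed nearest-TSS distances
#'
#' @param sites `GRanges`.
#' @param transcriptome a [Transcriptome].
#' @param flankBp histogram half-range (default 10 kb).
#' @param binBp bin width (default 500).
#' @return list with `bin_centers`, `counts`, `frequencies` (distances
#'   beyond the range are dropped), `n_sites`.
#' @export
tssDistanceProfile <- function(sites, transcriptome, flankBp = 10000L,
                               binBp = 500L) {
    centers <- GRanges(seqnames(sites),
                       IRanges(floor((start(sites) + end(sites)) / 2),
                               width = 1L),
                       seqinfo = seqinfo(sites))
    d <- .nearestTssDistance(centers, transcriptome)$distance
    # bins centered on multiples of binBp (a bin centered at 0), so
    # symmetric inputs give symmetric histograms
    breaks <- seq(-flankBp - binBp / 2, flankBp + binBp / 2,
                  by = binBp)
    keep <- !is.na(d) & d >= -flankBp & d <= flankBp
    counts <- as.numeric(table(cut(d[keep], breaks)))
    list(bin_centers = seq(-flankBp, flankBp, by = binBp),
         counts = counts, frequencies = counts / length(sites),
         n_sites = length(sites))
}

#' Map binding sites to target genes
#'
#' A site is linked to every gene whose strand-relative window
#' [TSS - `upstreamBp`, TES] (10 kb upstream through the gene body by
#' default) contains the site center. One site may link several genes
#' and vice versa.
#'
#' @param sites `GRanges` with an `id` mcol (added if absent).
#' @param transcriptome a [Transcriptome].
#' @param upstreamBp upstream window (default 10,000).
#' @return list with `links` (data.frame site_id, gene_symbol),
#'   `sitesPerGene` (named integer, every gene symbol present) and
#'   `genesPerSite` (named integer).
#' @export
mapTargets <- function(sites, transcriptome, upstreamBp = 10000L) {
    if (is.null(mcols(sites)$id))
        mcols(sites)$id <- sprintf("site_%05d", seq_along(sites))
    centers <- GRanges(seqnames(sites),
                       IRanges(floor((start(sites) + end(sites)) / 2),
                               width = 1L),
                       seqinfo = seqinfo(sites))
    g <- genes(transcriptome)
    minus <- as.character(strand(g)) == "-"
    ws <- ifelse(minus, start(g), pmax(start(g) - upstreamBp, 1L))
    lens <- seqlengths(seqinfo(g))[as.character(seqnames(g))]
    we <- ifelse(minus, pmin(end(g) + upstreamBp, lens), end(g))
    windows <- GRanges(seqnames(g), IRanges(ws, we), seqinfo = seqinfo(g))
    ov <- findOverlaps(centers, windows, ignore.strand = TRUE)
    links <- unique(data.frame(
        site_id = mcols(sites)$id[S4Vectors::queryHits(ov)],
        gene_symbol = mcols(g)$gene_symbol[S4Vectors::subjectHits(ov)],
        stringsAsFactors = FALSE))
    links <- links[order(links$site_id, links$gene_symbol), , drop = FALSE]
    rownames(links) <- NULL
    allGenes <- unique(mcols(g)$gene_symbol)
    spg <- table(factor(links$gene_symbol, levels = allGenes))
    gps <- table(factor(links$site_id, levels = mcols(sites)$id))
    list(links = links,
         sitesPerGene = stats::setNames(as.integer(spg), names(spg)),
         genesPerSite = stats::setNames(as.integer(gps), names(gps)))
}

#' Assign regulation groups to binding sites
#'
#' INDUCED if any linked gene is flagged up; else REPRESSED if any is
#' flagged down; else NO_CHANGE if any linked gene was measured; else
#' UNASSIGNED (no links, or links only to unmeasured genes). Sites
#' linked to both up and down genes are resolved by that precedence
#' and counted as conflicts.
#'
#' @param siteIds character vector of site ids (defines output order).
#' @param links data.frame from [mapTargets()].
#' @param deTable data.frame from [readDeTable()].
#' @return list with `groups` (factor per site), `n_conflicts`,
#'   `n_links_to_unknown_genes` (linked symbols absent from the table,
#'   treated as unmeasured).
#' @export
assignRegulationGroups <- function(siteIds, links, deTable) {
    dir <- stats::setNames(deTable$direction, deTable$gene)
    meas <- stats::setNames(deTable$measured == 1L, deTable$gene)
    known <- links$gene_symbol %in% deTable$gene
    nUnknown <- sum(!known)
    if (nUnknown)
        message(nUnknown, " link(s) to genes absent from the DE table ",
                "treated as unmeasured")
    ld <- ifelse(known, dir[links$gene_symbol], "unknown")
    lm <- ifelse(known, meas[links$gene_symbol], FALSE)
    up <- tapply(ld == "up", links$site_id, any)
    dn <- tapply(ld == "down", links$site_id, any)
    me <- tapply(lm, links$site_id, any)
    pick <- function(id) {
        if (!(id %in% names(up))) return("UNASSIGNED")
        if (isTRUE(up[[id]])) "INDUCED"
        else if (isTRUE(dn[[id]])) "REPRESSED"
        else if (isTRUE(me[[id]])) "NO_CHANGE"
        else "UNASSIGNED"
    }
    groups <- vapply(siteIds, pick, character(1))
    conflicts <- sum(vapply(siteIds, function(id)
        id %in% names(up) && isTRUE(up[[id]]) && isTRUE(dn[[id]]),
        logical(1)))
    list(groups = factor(groups, levels = REGULATION_LEVELS),
         n_conflicts = as.integer(conflicts),
         n_links_to_unknown_genes = as.integer(nUnknown))
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' p-value by summing hypergeometric probabilities not exceeding that
#' of the observed table (the classic two-sided rule); odds ratio is
#' the sample ratio ad/bc, reported as Inf when bc = 0 with ad > 0 and
#' NA when both diagonals contain a zero product.
#'
#' @param tab 2x2 matrix of non-negative integers (not all zero).
#' @return list with `table`, `odds_ratio`, `pvalue`.
#' @export
fisherEnrichment <- function(tab) {
    tab <- as.matrix(tab)
    stopifnot(all(dim(tab) == 2L), all(tab >= 0))
    if (sum(tab) == 0L) stop("all-zero table: Fisher test undefined")
    ad <- tab[1L, 1L] * tab[2L, 2L]
    bc <- tab[1L, 2L] * tab[2L, 1L]
    or <- if (bc == 0 && ad > 0) Inf else if (bc == 0 && ad == 0)
        NA_real_ else ad / bc
    p <- stats::fisher.test(tab)$p.value
    list(table = tab, odds_ratio = or, pvalue = p)
}

#' Gene-level binding enrichment per expression category
#'
#' For each regulation category of genes (up, down) and the all-genes
#' background, the percentage of genes with exactly 1, 2, or 3+
#' linked binding sites (and >= 1), plus a Fisher exact test of
#' bound/unbound in the category versus all other genes.
#'
#' @param deTable data.frame from [readDeTable()].
#' @param sitesPerGene named integer vector from [mapTargets()].
#' @return data.frame with one row per category.
#' @export
geneLevelEnrichment <- function(deTable, sitesPerGene) {
    cnt <- sitesPerGene[deTable$gene]
    cnt[is.na(cnt)] <- 0L
    cats <- list(up = deTable$direction == "up",
                 down = deTable$direction == "down",
                 all = rep(TRUE, nrow(deTable)))
    boundAll <- cnt >= 1L
    out <- do.call(rbind, lapply(names(cats), function(nm) {
        sel <- cats[[nm]]
        n <- sum(sel)
        if (n == 0L) return(NULL)
        pct <- function(k) 100 * sum(cnt[sel] == k) / n
        p <- if (nm == "all") NA_real_ else
            fisherEnrichment(matrix(c(sum(boundAll & sel),
                                      sum(!boundAll & sel),
                                      sum(boundAll & !sel),
                                      sum(!boundAll & !sel)),
                                    nrow = 2L, byrow = TRUE))$pvalue
        data.frame(category = nm, n_genes = n,
                   pct_1_site = pct(1L), pct_2_sites = pct(2L),
                   pct_3plus_sites = 100 * sum(cnt[sel] >= 3L) / n,
                   pct_bound = 100 * sum(boundAll & sel) / n,
                   fisher_p_vs_rest = p)
    }))
    rownames(out) <- NULL
    out
}

#' Cross-tabulation of binding and TATA status against regulation
#'
#' Genes are split into four groups by bound (any linked site) and
#' TATA status; induced and repressed percentages are reported per
#' group with Fisher exact tests against the unbound/TATA-less
#' reference group.
#'
#' @param deTable data.frame from [readDeTable()].
#' @param tataFlags named logical vector (gene symbol -> TATA flag).
#' @param boundFlags named logical vector (gene symbol -> bound flag).
#' @return data.frame, one row per group.
#' @export
crosstabTataCreb <- function(deTable, tataFlags, boundFlags) {
    tb <- tataFlags[deTable$gene]
    bb <- boundFlags[deTable$gene]
    tb[is.na(tb)] <- FALSE; bb[is.na(bb)] <- FALSE
    grp <- paste0(ifelse(bb, "bound", "unbound"), "/",
                  ifelse(tb, "TATA", "noTATA"))
    ref <- "unbound/noTATA"
    lv <- c("bound/TATA", "bound/noTATA", "unbound/TATA", ref)
    up <- deTable$direction == "up"
    dn <- deTable$direction == "down"
    out <- do.call(rbind, lapply(lv, function(g) {
        sel <- grp == g
        n <- sum(sel)
        fp <- function(flag) {
            if (g == ref || n == 0L) return(NA_real_)
            fisherEnrichment(matrix(c(sum(flag & sel), sum(!flag & sel),
                                      sum(flag & grp == ref),
                                      sum(!flag & grp == ref)),
                                    nrow = 2L, byrow = TRUE))$pvalue
        }
        data.frame(group = g, n_genes = n,
                   pct_induced = if (n) 100 * sum(up & sel) / n else NA,
                   pct_repressed = if (n) 100 * sum(dn & sel) / n else NA,
                   fisher_p_induced = fp(up),
                   fisher_p_repressed = fp(dn))
    }))
    rownames(out) <- NULL
    out
}

#' Average signal profiles around anchor groups
#'
#' RPM-scaled fragment-depth profile of a (secondary-factor) signal
#' library around each anchor center, binned and averaged within each
#' anchor group. Bins truncated at chromosome edges are excluded from
#' the mean for the affected anchors only. Also emits the per-anchor
#' peak height of the signal for box-plot style summaries.
#'
#' @param anchors `GRanges` of anchor regions (centers used).
#' @param groups vector of group labels, one per anchor.
#' @param lib signal [TagLibrary] (or list pooled with
#'   [poolLibraries()] first).
#' @param flankBp profile half-width (default 2000).
#' @param binBp bin width (default 25).
#' @param fragmentBp fragment extension (default 108).
#' @return list with `offsets` (bin centers), `profiles` (matrix group
#'   x bin of mean RPM), `n_anchors` per group, and `anchor_heights`
#'   (per-anchor signal height in RPM with the group label).
#' @export
averageProfile <- function(anchors, groups, lib, flankBp = 2000L,
                           binBp = 25L, fragmentBp = 108L) {
    stopifnot(length(groups) == length(anchors), flankBp %% binBp == 0L)
    cov <- .fragmentCoverage(lib, fragmentBp, rpm = TRUE)
    centers <- floor((start(anchors) + end(anchors)) / 2)
    chr <- as.character(seqnames(anchors))
    lens <- seqlengths(seqinfo(anchors))
    nBins <- 2L * flankBp / binBp
    M <- matrix(NA_real_, nrow = length(anchors), ncol = nBins)
    for (i in seq_along(anchors)) {
        ws <- centers[i] - flankBp
        we <- centers[i] + flankBp - 1L
        len <- lens[[chr[i]]]
        v <- rep(NA_real_, 2L * flankBp)
        lo <- max(ws, 1L); hi <- min(we, len)
        if (lo <= hi && chr[i] %in% names(cov))
            v[(lo - ws + 1L):(hi - ws + 1L)] <-
                as.numeric(cov[[chr[i]]][lo:hi])
        M[i, ] <- colMeans(matrix(v, nrow = binBp), na.rm = FALSE)
    }
    lv <- if (is.factor(groups)) levels(groups) else
        unique(as.character(groups))
    groups <- as.character(groups)
    prof <- do.call(rbind, lapply(lv, function(g) {
        sel <- groups == g
        if (!any(sel)) return(rep(NA_real_, nBins))
        colMeans(M[sel, , drop = FALSE], na.rm = TRUE)
    }))
    rownames(prof) <- lv
    heights <- regionHeight(anchors, lib, fragmentBp)
    list(offsets = seq(-flankBp, flankBp - binBp, by = binBp) + binBp / 2,
         profiles = prof,
         n_anchors = stats::setNames(
             vapply(lv, function(g) sum(groups == g), integer(1)), lv),
         anchor_heights = data.frame(group = groups, height_rpm = heights))
}
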