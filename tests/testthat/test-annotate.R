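# Feature classification, target mapping, regulation groups,
# enrichment statistics and co-localization profiles.

test_that("classifySite follows the promoter/UTR/exon/intron priority", {
    gi <- smallGenome(200000L)
    tr <- fixtureTranscriptome(gi)
    # gA: + strand, TSS 10,000, exon1 10,000-11,000, CDS from 10,501
    sites <- GRanges("chr1", IRanges(c(
        9500L,      # 500 bp upstream of gA TSS -> PROMOTER
        10300L,     # +300 of TSS, inside 5'UTR exon bases -> FIVE_UTR
        10100L,     # inside 5'UTR but within +200 of TSS -> PROMOTER
        12500L,     # coding exon 2 -> EXON_CDS
        11500L,     # intron 1 -> INTRON, first_intron
        13500L,     # intron 2 -> INTRON, not first
        14900L,     # 3'UTR bases of last exon -> THREE_UTR
        130000L     # 60 kb+ from every TSS -> INTERGENIC
    ), width = 1L), seqinfo = gi)
    ann <- classifySite(sites, tr)
    expect_equal(as.character(ann$feature),
                 c("PROMOTER", "FIVE_UTR", "PROMOTER", "EXON_CDS",
                   "INTRON", "INTRON", "THREE_UTR", "INTERGENIC"))
    expect_identical(ann$first_intron,
                     c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE,
                       FALSE, FALSE))
    expect_false(ann$within_50kb_tss[8])
    # minus-strand gene gB: TSS 65,000, first intron is the rightmost
    mAnn <- classifySite(GRanges("chr1", IRanges(c(65400L, 63500L),
                                                 width = 1L),
                                 seqinfo = gi), tr)
    expect_equal(as.character(mAnn$feature), c("PROMOTER", "INTRON"))
    expect_true(mAnn$first_intron[2])
    # every site gets exactly one class (partition property)
    set.seed(97)
    rnd <- GRanges("chr1", IRanges(sample.int(199000L, 300L),
                                   width = 1L), seqinfo = gi)
    f <- classifySite(rnd, tr)$feature
    expect_false(anyNA(f))
    expect_equal(sum(table(f)), 300L)
    # literal priority ranks INTRON above exonic classes
    lit <- classifySite(GRanges("chr1", IRanges(12500L, width = 1L),
                                seqinfo = gi), tr, mode = "literal")
    expect_equal(as.character(lit$feature), "EXON_CDS")
})

test_that("the regulatory-context classifier separates proximal and
           distal promoters", {
    gi <- smallGenome(200000L)
    tr <- fixtureTranscriptome(gi)
    cls <- classifySiteRegulatory(GRanges("chr1", IRanges(c(
        9500L,   # -500 -> PROXIMAL
        4000L,   # -6 kb -> DISTAL
        11500L,  # intron -> INTRONIC
        12500L,  # exon -> EXONIC
        130000L  # nothing -> OTHER
    ), width = 1L), seqinfo = gi), tr)
    expect_equal(as.character(cls),
                 c("PROXIMAL", "DISTAL", "INTRONIC", "EXONIC",
                   "OTHER"))
})

test_that("tssDistanceProfile matches a linear-scan oracle", {
    gi <- smallGenome(200000L)
    tr <- fixtureTranscriptome(gi)
    tss <- mcols(genes(tr))$tss
    sites <- GRanges("chr1", IRanges(tss, width = 1L), seqinfo = gi)
    h <- tssDistanceProfile(sites, tr, flankBp = 1000L, binBp = 100L)
    expect_equal(sum(h$counts), length(tss))
    expect_equal(h$counts[which(h$bin_centers == 0)],
                 as.numeric(length(tss)))
    # symmetric planted offsets produce a symmetric histogram
    sym <- GRanges("chr1", IRanges(c(tss + 1000L, tss - 1000L),
                                   width = 1L), seqinfo = gi)
    hs <- tssDistanceProfile(sym, tr, flankBp = 2000L, binBp = 200L)
    expect_equal(hs$counts, rev(hs$counts))
    # random fixture vs direct nearest-TSS brute force
    set.seed(101)
    rnd <- GRanges("chr1", IRanges(sample.int(199000L, 200L),
                                   width = 1L), seqinfo = gi)
    hr <- tssDistanceProfile(rnd, tr, flankBp = 5000L, binBp = 500L)
    g <- genes(tr)
    brute <- vapply(start(rnd), function(p) {
        d <- abs(p - tss)
        i <- which.min(d)
        if (as.character(strand(g))[i] == "-") tss[i] - p else
            p - tss[i]
    }, numeric(1))
    keep <- brute >= -5000 & brute <= 5000
    expect_equal(sum(hr$counts), sum(keep))
})

test_that("mapTargets links sites within 10 kb upstream or the gene
           body, boundaries exact", {
    gi <- smallGenome(200000L)
    tr <- fixtureTranscriptome(gi)
    # gA (+): TSS 10,000, body to 15,000; gB (-): TSS 65,000
    sites <- GRanges("chr1", IRanges(c(
        10000L - 9999L,   # 9,999 bp upstream of gA -> linked
        65000L + 10000L,  # exactly 10 kb upstream of gB -> linked
        65000L + 10001L,  # 10,001 bp upstream of gB -> unlinked
        14999L,           # inside gA body -> linked
        65000L + 9999L    # 9,999 upstream of minus-strand gB
    ), width = 1L), seqinfo = gi)
    mcols(sites)$id <- sprintf("s%d", 1:5)
    mt <- mapTargets(sites, tr)
    linked <- function(id, gene)
        any(mt$links$site_id == id & mt$links$gene_symbol == gene)
    expect_true(linked("s1", "gA"))
    expect_true(linked("s2", "gB"))
    expect_false(linked("s3", "gB"))
    expect_true(linked("s4", "gA"))
    expect_true(linked("s5", "gB"))
    # bipartite symmetry: both marginal tables describe the same graph
    expect_equal(sum(mt$sitesPerGene), nrow(mt$links))
    expect_equal(sum(mt$genesPerSite), nrow(mt$links))
    # random fixture vs all-pairs window oracle
    set.seed(103)
    rnd <- GRanges("chr1", IRanges(sample.int(199000L, 200L),
                                   width = 1L), seqinfo = gi)
    mcols(rnd)$id <- sprintf("r%03d", seq_along(rnd))
    mtr <- mapTargets(rnd, tr)
    g <- genes(tr)
    for (j in seq_along(g)) {
        win <- if (as.character(strand(g))[j] == "+")
            c(start(g)[j] - 10000L, end(g)[j]) else
            c(start(g)[j], end(g)[j] + 10000L)
        brute <- sum(start(rnd) >= win[1] & start(rnd) <= win[2])
        expect_equal(unname(mtr$sitesPerGene[
            mcols(g)$gene_symbol[j]]), brute)
    }
})

test_that("assignRegulationGroups applies the documented precedence", {
    links <- data.frame(
        site_id = c("s1", "s2", "s2", "s3", "s5", "s5"),
        gene_symbol = c("up1", "up1", "dn1", "nc1", "mystery", "nc1"))
    de <- data.frame(gene = c("up1", "dn1", "nc1"),
                     log2fc = c(1, -1, 0),
                     direction = c("up", "down", "none"),
                     measured = c(1L, 1L, 1L))
    expect_message(
        r <- assignRegulationGroups(paste0("s", 1:5), links, de),
        "absent from the DE table")
    expect_equal(as.character(r$groups),
                 c("INDUCED", "INDUCED", "NO_CHANGE", "UNASSIGNED",
                   "NO_CHANGE"))
    expect_equal(r$n_conflicts, 1L)   # s2 links both up and down
    expect_equal(r$n_links_to_unknown_genes, 1L)
    # partition property on a random fixture against a rule oracle
    set.seed(107)
    genesAll <- sprintf("g%02d", 1:20)
    deR <- data.frame(gene = genesAll, log2fc = 0,
                      direction = sample(c("up", "down", "none"), 20L,
                                         replace = TRUE,
                                         prob = c(.2, .2, .6)),
                      measured = rbinom(20L, 1L, 0.8))
    deR$direction[deR$measured == 0L] <- "none"
    siteIds <- sprintf("x%02d", 1:30)
    linkR <- data.frame(
        site_id = sample(siteIds, 50L, replace = TRUE),
        gene_symbol = sample(genesAll, 50L, replace = TRUE))
    rr <- assignRegulationGroups(siteIds, linkR, deR)
    oracle <- vapply(siteIds, function(s) {
        gs <- linkR$gene_symbol[linkR$site_id == s]
        if (!length(gs)) return("UNASSIGNED")
        dirs <- deR$direction[match(gs, deR$gene)]
        meas <- deR$measured[match(gs, deR$gene)] == 1L
        if (any(dirs == "up")) "INDUCED"
        else if (any(dirs == "down")) "REPRESSED"
        else if (any(meas)) "NO_CHANGE"
        else "UNASSIGNED"
    }, character(1))
    expect_equal(as.character(rr$groups), unname(oracle))
    expect_equal(sum(table(rr$groups)), length(siteIds))
})

test_that("fisherEnrichment agrees with hypergeometric enumeration", {
    r <- fisherEnrichment(matrix(c(5, 5, 5, 5), 2L))
    expect_equal(r$odds_ratio, 1)
    expect_equal(r$pvalue, 1)
    r <- fisherEnrichment(matrix(c(5, 0, 0, 5), 2L))
    expect_equal(r$pvalue, 2 / choose(10, 5), tolerance = 1e-12)
    expect_equal(r$odds_ratio, Inf)
    expect_error(fisherEnrichment(matrix(0, 2L, 2L)), "all-zero")
    set.seed(109)
    for (i in 1:200) {
        tab <- matrix(rpois(4L, 8), 2L)
        if (sum(tab) == 0) next
        expect_equal(fisherEnrichment(tab)$pvalue,
                     oracleFisherP(tab[1, 1], tab[1, 2], tab[2, 1],
                                   tab[2, 2]),
                     tolerance = 1e-9)
    }
})

test_that("geneLevelEnrichment counts bound genes per category", {
    de <- data.frame(gene = sprintf("g%d", 1:10), log2fc = 0,
                     direction = c(rep("up", 3), rep("down", 2),
                                   rep("none", 5)),
                     measured = 1L)
    spg <- stats::setNames(c(1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L),
                           de$gene)
    e <- geneLevelEnrichment(de, spg)
    expect_equal(e$pct_1_site, rep(100, 3))
    expect_equal(e$pct_bound, rep(100, 3))
    # counting oracle with a structured fixture
    spg2 <- stats::setNames(c(2L, 0L, 3L, 1L, 0L, 0L, 1L, 0L, 0L, 4L),
                            de$gene)
    e2 <- geneLevelEnrichment(de, spg2)
    up <- spg2[1:3]
    expect_equal(e2$pct_1_site[e2$category == "up"],
                 100 * sum(up == 1L) / 3)
    expect_equal(e2$pct_3plus_sites[e2$category == "up"],
                 100 * sum(up >= 3L) / 3)
    expect_equal(e2$pct_bound[e2$category == "all"],
                 100 * mean(spg2 >= 1L))
    # Fisher direction is computable and in range
    expect_true(all(is.na(e2$fisher_p_vs_rest) |
                    (e2$fisher_p_vs_rest > 0 &
                     e2$fisher_p_vs_rest <= 1)))
})

test_that("crosstabTataCreb splits genes into four groups with exact
           percentages", {
    genes <- sprintf("g%02d", 1:40)
    de <- data.frame(gene = genes, log2fc = 0,
                     direction = rep(c("up", "none", "none", "down"),
                                     10L),
                     measured = 1L)
    tata <- stats::setNames(rep(c(TRUE, FALSE), 20L), genes)
    bound <- stats::setNames(rep(c(TRUE, TRUE, FALSE, FALSE), 10L),
                             genes)
    ct <- crosstabTataCreb(de, tata, bound)
    expect_equal(nrow(ct), 4L)
    expect_equal(sum(ct$n_genes), 40L)
    # cross-tabulation oracle for one cell
    sel <- bound & tata
    expect_equal(ct$pct_induced[ct$group == "bound/TATA"],
                 100 * sum(de$direction == "up" & sel) / sum(sel))
    # perfectly uniform DE rates: reference tests near 1
    deU <- de; deU$direction <- rep(c("up", "none"), 20L)
    tataU <- stats::setNames(rep(c(TRUE, FALSE), each = 20L), genes)
    boundU <- stats::setNames(rep(rep(c(TRUE, FALSE), each = 10L),
                                  2L), genes)
    ctU <- crosstabTataCreb(deU, tataU, boundU)
    expect_true(all(ctU$fisher_p_induced >= 0.999,
                    na.rm = TRUE))
})

test_that("averageProfile reproduces single-anchor coverage and
           handles edges", {
    gi <- smallGenome(20000L)
    set.seed(113)
    lib <- libFromPositions(
        c(9900L + sample.int(200L, 100L, replace = TRUE),
          sample.int(20000L, 200L, replace = TRUE)),
        sample(c("+", "-"), 300L, replace = TRUE), gi)
    anchor <- GRanges("chr1", IRanges(10000L, width = 1L),
                      seqinfo = gi)
    pr <- averageProfile(anchor, "G", lib, flankBp = 500L,
                         binBp = 25L)
    # n = 1: profile equals that anchor's binned RPM coverage
    depth <- oraclePileup(tagDf(tags(lib)), 108L, 20000L) *
        1e6 / nTags(lib)
    win <- depth[(10000L - 500L):(10000L + 499L)]
    oracle <- colMeans(matrix(win, nrow = 25L))
    expect_equal(unname(pr$profiles["G", ]), oracle)
    expect_gt(max(pr$profiles["G", ]), mean(depth))
    # zero-signal library gives all-zero profiles
    quiet <- libFromPositions(5000L, "+", gi)
    far <- GRanges("chr1", IRanges(15000L, width = 1L),
                   seqinfo = gi)
    pz <- averageProfile(far, "G", quiet, flankBp = 500L,
                         binBp = 25L)
    expect_true(all(pz$profiles == 0))
    # anchors at the chromosome edge: truncated bins are NaN-free in
    # groups containing interior anchors and excluded otherwise
    edge <- GRanges("chr1", IRanges(c(100L, 10000L), width = 1L),
                    seqinfo = gi)
    pe <- averageProfile(edge, c("E", "G"), lib, flankBp = 500L,
                         binBp = 25L)
    expect_true(anyNA(pe$profiles["E", ]))   # truncated-only bins
    expect_false(anyNA(pe$profiles["G", ]))
    expect_equal(unname(pe$n_anchors), c(1L, 1L))
})
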