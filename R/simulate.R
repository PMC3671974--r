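# Seeded synthetic-data generator. Every artifact of a run is a pure
# function of (config, seed): a shared deterministic layout step places
# genes, sites and expression truth, and each emitter derives its own
# stream from config@seed, so the individually exported generators are
# mutually consistent.

#' Build a simulation configuration
#'
#' See [SimulationConfig] for the meaning and defaults of every field;
#' the defaults encode the study conditions the pipeline assumes
#' (5 + 5 replicates, 200 true sites, 20 single-replicate artifacts,
#' median 1.3-fold condition effect, 20% TATA promoters, DE calls at
#' |fold change| >= 1.5, 60% of DE genes vs 33% of others bound).
#'
#' @param ... named overrides of [SimulationConfig] slots.
#' @return a validated [SimulationConfig].
#' @examples
#' cfg <- simulationConfig(seed = 7L, nTrueSites = 50L)
#' @export
simulationConfig <- function(...) {
    args <- list(...)
    intSlots <- c("nChroms", "chromBp", "nGenes", "nTrueSites",
                  "nArtifactSites", "nReplicates", "depthPerReplicate",
                  "fragmentBp", "minSiteSpacingBp", "seed")
    for (s in intSlots) if (s %in% names(args))
        args[[s]] <- as.integer(args[[s]])
    do.call(new, c(list("SimulationConfig"), args))
}

CONDITIONS <- c("fasted", "refed")

# ---- deterministic layout: genes, expression truth, site placement ----

.layoutStudy <- function(config) {
    set.seed(config@seed)
    margin <- 10000L
    nChrom <- config@nChroms
    chromLen <- config@chromBp
    chromNames <- sprintf("chr%d", seq_len(nChrom))
    genome <- genomeIndex(stats::setNames(rep(chromLen, nChrom),
                                          chromNames))

    # -- gene structures (exon/intron part lists, transcription order) --
    nGenes <- config@nGenes
    perChrom <- diff(round(seq(0, nGenes, length.out = nChrom + 1L)))
    geneRows <- list()
    gi <- 0L
    for (ci in seq_len(nChrom)) {
        n <- perChrom[ci]
        if (n == 0L) next
        nEx <- sample(2:8, n, replace = TRUE)
        spans <- integer(n)
        parts <- vector("list", n)
        for (i in seq_len(n)) {
            exW <- sample(80:150, nEx[i], replace = TRUE)
            inW <- if (nEx[i] > 1L)
                sample(80:200, nEx[i] - 1L, replace = TRUE) else integer(0)
            parts[[i]] <- list(exW = exW, inW = inW)
            spans[i] <- sum(exW) + sum(inW)
        }
        # gaps wide enough that 10 kb target windows of adjacent genes
        # never cross-link a site planted within TSS-2kb..TES
        minGap <- 12200L
        leftover <- chromLen - 2L * margin - sum(spans) -
            minGap * (n + 1L)
        if (leftover < 0L)
            stop("genome capacity overflow: too many/large genes for ",
                 chromNames[ci])
        cuts <- sort(sample.int(leftover + 1L, n, replace = TRUE) - 1L)
        extra <- diff(c(0L, cuts, leftover))
        pos <- margin
        for (i in seq_len(n)) {
            pos <- pos + minGap + extra[i]
            txStart <- pos + 1L
            txEnd <- pos + spans[i]
            pos <- txEnd
            gi <- gi + 1L
            strand <- sample(c("+", "-"), 1L)
            exW <- parts[[i]]$exW; inW <- parts[[i]]$inW
            # genomic-order exon bounds
            widths <- integer(0)
            for (k in seq_along(exW)) {
                widths <- c(widths, exW[k])
                if (k < length(exW)) widths <- c(widths, inW[k])
            }
            bounds <- txStart + c(0L, cumsum(widths))
            exStarts <- bounds[seq(1L, by = 2L, length.out = length(exW))]
            exEnds <- exStarts + exW - 1L
            # UTRs live in the first/last transcription-order exon
            utr5 <- sample(30:70, 1L)
            utr3 <- sample(30:70, 1L)
            utr5 <- min(utr5, exW[1L] - 20L)
            utr3 <- min(utr3, exW[length(exW)] - 20L)
            if (strand == "+") {
                cdsStart <- exStarts[1L] + utr5
                cdsEnd <- exEnds[length(exEnds)] - utr3
            } else {
                cdsStart <- exStarts[1L] + utr3
                cdsEnd <- exEnds[length(exEnds)] - utr5
            }
            geneRows[[gi]] <- data.frame(
                gene = sprintf("gene%04d", gi),
                tx = sprintf("tx%04d", gi),
                chrom = chromNames[ci], strand = strand,
                txStart = txStart - 1L, txEnd = txEnd,
                cdsStart = cdsStart - 1L, cdsEnd = cdsEnd,
                exonCount = length(exW),
                exonStarts = paste0(paste(exStarts - 1L,
                                          collapse = ","), ","),
                exonEnds = paste0(paste(exEnds, collapse = ","), ","),
                stringsAsFactors = FALSE)
        }
    }
    geneTab <- do.call(rbind, geneRows)
    tss <- ifelse(geneTab$strand == "-", geneTab$txEnd,
                  geneTab$txStart + 1L)
    tes <- ifelse(geneTab$strand == "-", geneTab$txStart + 1L,
                  geneTab$txEnd)

    # -- expression truth --
    nG <- nrow(geneTab)
    measured <- stats::runif(nG) < config@fracMeasured
    de <- rep("none", nG)
    deCand <- which(measured)
    nDe <- round(config@fracDeGenes * nG)
    deIdx <- sample(deCand, min(nDe, length(deCand)))
    de[deIdx] <- sample(c("up", "down"), length(deIdx), replace = TRUE)
    log2fc <- stats::rnorm(nG, 0, 0.15)
    log2fc <- pmin(pmax(log2fc, -0.55), 0.55)   # |FC| < 1.5 for non-DE
    amp <- log2(config@deFoldMin) + abs(stats::rnorm(nG, 0, 0.6))
    log2fc[de == "up"] <- amp[de == "up"]
    log2fc[de == "down"] <- -amp[de == "down"]
    tata <- stats::runif(nG) < config@fracTata

    # -- bound-gene selection and site placement --
    isDe <- de != "none"
    bound <- logical(nG)
    bound[isDe] <- stats::runif(sum(isDe)) < config@fracDeBound
    bound[!isDe] <- stats::runif(sum(!isDe)) < config@fracBgBound
    nBound <- sum(bound)
    if (nBound > config@nTrueSites) {
        # keep the configured number of true sites: drop excess at random
        drop <- sample(which(bound), nBound - config@nTrueSites)
        bound[drop] <- FALSE
        nBound <- sum(bound)
    }
    spacing <- max(config@minSiteSpacingBp, 2L * config@fragmentBp)
    placedPos <- stats::setNames(vector("list", nChrom), chromNames)
    siteChrom <- character(0); sitePos <- integer(0)
    linkedGene <- character(0)
    okSpacing <- function(ch, p) {
        q <- placedPos[[ch]]
        !length(q) || min(abs(q - p)) > spacing
    }
    addSite <- function(ch, p) {
        placedPos[[ch]] <<- c(placedPos[[ch]], p)
        siteChrom <<- c(siteChrom, ch); sitePos <<- c(sitePos, p)
    }
    for (i in which(bound)) {
        ch <- geneTab$chrom[i]
        win <- if (geneTab$strand[i] == "+")
            c(max(geneTab$txStart[i] + 1L - 2000L, margin),
              geneTab$txEnd[i])
        else
            c(geneTab$txStart[i] + 1L,
              min(geneTab$txEnd[i] + 2000L, chromLen - margin))
        done <- FALSE
        for (try in 1:200) {
            p <- sample(win[1L]:win[2L], 1L)
            if (okSpacing(ch, p)) { addSite(ch, p); done <- TRUE; break }
        }
        if (!done) { bound[i] <- FALSE; next }
        linkedGene <- c(linkedGene, geneTab$gene[i])
    }
    # leftover true sites and artifacts are placed outside every
    # target window (TSS - 10 kb through TES) so the planted
    # bound-gene structure is recoverable from the emitted files
    winStart <- ifelse(geneTab$strand == "+",
                       pmax(geneTab$txStart + 1L - 10000L, 1L),
                       geneTab$txStart + 1L)
    winEnd <- ifelse(geneTab$strand == "+", geneTab$txEnd,
                     pmin(geneTab$txEnd + 10000L, chromLen))
    freeByChrom <- lapply(chromNames, function(ch) {
        sel <- geneTab$chrom == ch
        IRanges::setdiff(
            IRanges(margin, chromLen - margin),
            IRanges::reduce(IRanges(winStart[sel] - 200L,
                                    winEnd[sel] + 200L)))
    })
    names(freeByChrom) <- chromNames
    freeWidth <- vapply(freeByChrom, function(x) sum(width(x)),
                        numeric(1))
    nLeft <- config@nTrueSites - length(sitePos)
    sampleFree <- function() {
        for (try in 1:1000) {
            ch <- sample(chromNames, 1L, prob = freeWidth / sum(freeWidth))
            fr <- freeByChrom[[ch]]
            iv <- sample.int(length(fr), 1L,
                             prob = width(fr) / sum(width(fr)))
            p <- start(fr)[iv] + sample.int(width(fr)[iv], 1L) - 1L
            if (okSpacing(ch, p)) return(list(ch = ch, p = p))
        }
        stop("site placement failed: genome too crowded for the ",
             "configured site count and spacing")
    }
    if (nLeft > 0L) for (k in seq_len(nLeft)) {
        f <- sampleFree(); addSite(f$ch, f$p)
        linkedGene <- c(linkedGene, NA_character_)
    }
    nTrue <- length(sitePos)
    # artifact sites, each owned by one (condition, replicate)
    artChrom <- character(0); artPos <- integer(0)
    if (config@nArtifactSites > 0L)
        for (k in seq_len(config@nArtifactSites)) {
            f <- sampleFree(); addSite(f$ch, f$p)
            artChrom <- c(artChrom, f$ch); artPos <- c(artPos, f$p)
        }
    ownerCond <- if (config@nArtifactSites > 0L)
        sample(CONDITIONS, config@nArtifactSites, replace = TRUE) else
        character(0)
    ownerRep <- if (config@nArtifactSites > 0L)
        sample(seq_len(config@nReplicates), config@nArtifactSites,
               replace = TRUE) else integer(0)

    # per-site condition fold (fasted / re-fed), log-normal in log2
    fold <- 2^stats::rnorm(nTrue, log2(config@globalFoldMedian),
                           config@foldLog2Sd)
    motif <- sample(c("full", "half", "none"), nTrue, replace = TRUE,
                    prob = config@motifMix)

    sites <- GRanges(
        c(siteChrom[seq_len(nTrue)], artChrom),
        IRanges(c(sitePos[seq_len(nTrue)], artPos), width = 1L),
        seqinfo = genome)
    mcols(sites) <- DataFrame(
        site_id = sprintf("truth_%04d", seq_along(sites)),
        type = c(rep("true", nTrue),
                 rep("artifact", config@nArtifactSites)),
        fold = c(fold, rep(NA_real_, config@nArtifactSites)),
        motif = c(motif, rep("none", config@nArtifactSites)),
        owner_condition = c(rep(NA_character_, nTrue), ownerCond),
        owner_replicate = c(rep(NA_integer_, nTrue),
                            sprintf("rep%d", ownerRep)),
        linked_gene = c(linkedGene, rep(NA_character_,
                                        config@nArtifactSites)))
    geneDf <- DataFrame(
        gene = geneTab$gene, chrom = geneTab$chrom,
        strand = geneTab$strand, tss = tss, tes = tes,
        tata = tata, de = de, log2fc = log2fc,
        measured = as.integer(measured), bound = bound)
    list(genome = genome, geneTab = geneTab, genes = geneDf,
         sites = sites, config = config)
}

# ---- sequence emission with planted motifs ----

TATA_PLANT <- "GTATAAAAGGGGG"   # consensus of the shipped TATA PWM

.plant <- function(chars, at, motif) {
    # place motif so its center covers position `at`
    s <- at - floor((nchar(motif) - 1L) / 2)
    chars[s:(s + nchar(motif) - 1L)] <- strsplit(motif, "")[[1L]]
    chars
}

# scrub unintended CRE matches from a +/-60 bp neighbourhood of a true
# site center so the planted motif class is the measured class
.scrubCre <- function(chars, center, protectRange) {
    lo <- max(1L, center - 60L); hi <- min(length(chars), center + 60L)
    for (iter in 1:50) {
        win <- Biostrings::DNAString(paste(chars[lo:hi], collapse = ""))
        bad <- integer(0)
        m <- Biostrings::matchPattern(CRE_OCTAMER, win, max.mismatch = 1)
        m <- m[Biostrings::start(m) >= 1L &
               Biostrings::end(m) <= length(win)]
        for (k in seq_along(m)) {
            posns <- (lo + Biostrings::start(m)[k] - 1L):
                (lo + Biostrings::end(m)[k] - 1L)
            posns <- setdiff(posns, protectRange)
            bad <- c(bad, posns)
        }
        for (p in CRE_HALF_SITES) {
            m <- Biostrings::matchPattern(p, win)
            for (k in seq_along(m)) {
                posns <- (lo + Biostrings::start(m)[k] - 1L):
                    (lo + Biostrings::end(m)[k] - 1L)
                posns <- setdiff(posns, protectRange)
                bad <- c(bad, posns)
            }
        }
        if (!length(bad)) return(chars)
        flip <- sample(unique(bad), 1L)
        chars[flip] <- sample(setdiff(c("A", "C", "G", "T"),
                                      chars[flip]), 1L)
    }
    chars
}

.buildSequence <- function(layout, config) {
    set.seed(config@seed + 1L)
    genome <- layout$genome
    chromNames <- GenomeInfoDb::seqnames(genome)
    seqs <- vector("list", length(chromNames))
    names(seqs) <- chromNames
    for (ch in chromNames)
        seqs[[ch]] <- sample(c("A", "C", "G", "T"),
                             seqlengths(genome)[[ch]], replace = TRUE)
    # plant TATA boxes ~30 bp upstream of flagged TSSs
    g <- layout$genes
    for (i in which(g$tata)) {
        off <- sample(25:35, 1L)
        at <- if (g$strand[i] == "+") g$tss[i] - off else g$tss[i] + off
        seqs[[g$chrom[i]]] <- .plant(seqs[[g$chrom[i]]], at, TATA_PLANT)
    }
    # plant CRE motifs at true site centers, then scrub accidental
    # matches around every planted site (including "none" sites)
    s <- layout$sites
    sChr <- as.character(seqnames(s)); sPos <- start(s)
    sMotif <- mcols(s)$motif
    protect <- vector("list", length(s))
    for (i in seq_along(s)) {
        motif <- switch(sMotif[i], full = CRE_OCTAMER,
                        half = CRE_HALF_SITES[1L], none = NULL)
        if (!is.null(motif)) {
            st <- sPos[i] - floor((nchar(motif) - 1L) / 2)
            protect[[i]] <- st:(st + nchar(motif) - 1L)
            seqs[[sChr[i]]] <- .plant(seqs[[sChr[i]]], sPos[i], motif)
        } else protect[[i]] <- integer(0)
    }
    for (i in seq_along(s))
        seqs[[sChr[i]]] <- .scrubCre(seqs[[sChr[i]]], sPos[i],
                                     protect[[i]])
    out <- Biostrings::DNAStringSet(vapply(seqs, paste, character(1),
                                           collapse = ""))
    names(out) <- chromNames
    out
}

# ---- tag emission ----

# mean site tag count per replicate implied by an enrichment fold:
# fold x background density x fragment footprint (2 x fragment_bp)
.siteMu <- function(config, fold) {
    bgDensity <- config@depthPerReplicate /
        (as.numeric(config@nChroms) * config@chromBp)
    fold * bgDensity * 2 * config@fragmentBp
}

# draw tag 5' positions around a site center: uniform over
# [center - fragment, center - 1] on +, mirrored on -
.siteTags <- function(n, center, fragmentBp) {
    if (n == 0L) return(data.frame(pos = integer(0),
                                   strand = character(0)))
    plus <- stats::runif(n) < 0.5
    off <- sample.int(fragmentBp, n, replace = TRUE)
    data.frame(pos = ifelse(plus, center - off, center + off),
               strand = ifelse(plus, "+", "-"))
}

.emitLibrary <- function(layout, config, cond, rep, includeArtifacts) {
    s <- layout$sites
    genome <- layout$genome
    true <- which(mcols(s)$type == "true")
    fold <- mcols(s)$fold[true]
    condFactor <- if (cond == CONDITIONS[1L]) sqrt(fold) else
        1 / sqrt(fold)
    mu <- .siteMu(config, config@enrichmentFold) * condFactor
    nSite <- stats::rpois(length(true), mu)
    centers <- start(s)[true]
    chr <- as.character(seqnames(s))[true]
    pos <- integer(0); strandV <- character(0); chrV <- character(0)
    for (i in seq_along(true)) {
        t <- .siteTags(nSite[i], centers[i], config@fragmentBp)
        pos <- c(pos, t$pos); strandV <- c(strandV, t$strand)
        chrV <- c(chrV, rep(chr[i], nSite[i]))
    }
    if (includeArtifacts) {
        art <- which(mcols(s)$type == "artifact" &
                     mcols(s)$owner_condition == cond &
                     mcols(s)$owner_replicate == sprintf("rep%d", rep))
        for (i in art) {
            n <- stats::rpois(1L, .siteMu(config, config@artifactFold))
            t <- .siteTags(n, start(s)[i], config@fragmentBp)
            pos <- c(pos, t$pos); strandV <- c(strandV, t$strand)
            chrV <- c(chrV, rep(as.character(seqnames(s))[i], n))
        }
    }
    nBg <- config@depthPerReplicate - length(pos)
    if (nBg < 0L)
        stop("site tags exceed configured depth; lower enrichment ",
             "or raise depthPerReplicate")
    lens <- seqlengths(genome)
    chIdx <- sample.int(length(lens), nBg, replace = TRUE,
                        prob = lens / sum(lens))
    bgPos <- floor(stats::runif(nBg) * lens[chIdx]) + 1L
    chrV <- c(chrV, names(lens)[chIdx])
    pos <- c(pos, bgPos)
    strandV <- c(strandV, sample(c("+", "-"), nBg, replace = TRUE))
    pos <- pmin(pmax(pos, 1L), lens[chrV])
    gr <- GRanges(chrV, IRanges(pos, width = 1L), strand = strandV,
                  seqinfo = genome)
    new("TagLibrary", tags = sort(gr, ignore.strand = TRUE),
        replicateId = sprintf("rep%d", rep), condition = cond,
        deduplicated = FALSE)
}

# ---- exported generators (all consistent through the shared layout) ----

#' Simulate the genome sequence with planted motifs
#'
#' I.i.d. uniform background sequence; the configured CRE motif (full
#' octamer, forward half site, or none) is embedded at each true site
#' center, a TATA box is planted 25-35 bp upstream of flagged TSSs,
#' and accidental CRE matches near planted sites are scrubbed so the
#' planted motif class is the measured class. Byte-identical across
#' runs with the same config.
#'
#' @param config a [SimulationConfig].
#' @return list with `sequence` (DNAStringSet), `genome` (Seqinfo) and
#'   `truth` (a [TruthSet]).
#' @export
simulateGenome <- function(config = simulationConfig()) {
    layout <- .layoutStudy(config)
    list(sequence = .buildSequence(layout, config),
         genome = layout$genome,
         truth = new("TruthSet", sites = layout$sites,
                     genes = layout$genes, config = config))
}

#' Simulate the transcriptome
#'
#' Genes with 2-8 exons and random strand, placed with >= 2 kb gaps;
#' `fracTata` of them carry a planted TATA box upstream of the TSS
#' (truth flags recorded in the [TruthSet]).
#'
#' @param config a [SimulationConfig].
#' @return list with `transcriptome` ([Transcriptome]) and `truth`.
#' @export
simulateTranscriptome <- function(config = simulationConfig()) {
    layout <- .layoutStudy(config)
    list(transcriptome = transcriptomeFromTable(layout$geneTab,
                                                layout$genome),
         truth = new("TruthSet", sites = layout$sites,
                     genes = layout$genes, config = config))
}

#' Simulate the replicated ChIP tag libraries
#'
#' Background tags are uniform; each true site receives
#' Poisson-distributed tags around its center (5' ends uniform within
#' one fragment length, giving a summit at the center) at a rate set
#' by `enrichmentFold`, with condition rates scaled so the across-site
#' fasted/re-fed fold distribution has the configured median. Each
#' artifact site's tags are drawn only in its owning replicate of its
#' owning condition. Every emitted library holds exactly
#' `depthPerReplicate` tags (before deduplication).
#'
#' @param config a [SimulationConfig].
#' @return list of two lists of [TagLibrary] (`fasted`, `refed`), each
#'   of length `nReplicates`.
#' @export
simulateChipReplicates <- function(config = simulationConfig()) {
    layout <- .layoutStudy(config)
    set.seed(config@seed + 2L)
    out <- lapply(CONDITIONS, function(cond)
        lapply(seq_len(config@nReplicates), function(r)
            .emitLibrary(layout, config, cond, r, TRUE)))
    names(out) <- CONDITIONS
    out
}

#' Simulate the differential-expression gene table
#'
#' `fracDeGenes` of measured genes are flagged up or down with
#' |log2 fold change| >= log2(`deFoldMin`); binding truth is coupled
#' through the layout (a configurable fraction of DE and background
#' genes carry a planted site in their 10 kb-upstream/gene-body
#' window).
#'
#' @param config a [SimulationConfig].
#' @return data.frame with columns gene, log2fc, direction, measured.
#' @export
simulateDeTable <- function(config = simulationConfig()) {
    g <- .layoutStudy(config)$genes
    data.frame(gene = g$gene, log2fc = g$log2fc, direction = g$de,
               measured = g$measured, stringsAsFactors = FALSE)
}

#' Simulate a co-localized secondary-factor library
#'
#' Tags concentrate at true sites whose planted gene is up-regulated
#' (the induced arm of the study); elsewhere the library is uniform
#' background. Used to exercise group-wise co-localization profiles.
#'
#' @param config a [SimulationConfig].
#' @return a [TagLibrary].
#' @export
simulateSecondaryFactor <- function(config = simulationConfig()) {
    .secondaryFromLayout(.layoutStudy(config), config)
}

.secondaryFromLayout <- function(layout, config) {
    set.seed(config@seed + 3L)
    s <- layout$sites
    g <- layout$genes
    upGenes <- g$gene[g$de == "up"]
    sel <- which(mcols(s)$type == "true" &
                 !is.na(mcols(s)$linked_gene) &
                 mcols(s)$linked_gene %in% upGenes)
    genome <- layout$genome
    mu <- .siteMu(config, config@enrichmentFold)
    pos <- integer(0); strandV <- character(0); chrV <- character(0)
    for (i in sel) {
        n <- stats::rpois(1L, mu)
        t <- .siteTags(n, start(s)[i], config@fragmentBp)
        pos <- c(pos, t$pos); strandV <- c(strandV, t$strand)
        chrV <- c(chrV, rep(as.character(seqnames(s))[i], n))
    }
    nBg <- config@depthPerReplicate - length(pos)
    lens <- seqlengths(genome)
    chIdx <- sample.int(length(lens), nBg, replace = TRUE,
                        prob = lens / sum(lens))
    chrV <- c(chrV, names(lens)[chIdx])
    pos <- c(pos, floor(stats::runif(nBg) * lens[chIdx]) + 1L)
    strandV <- c(strandV, sample(c("+", "-"), nBg, replace = TRUE))
    pos <- pmin(pmax(pos, 1L), lens[chrV])
    gr <- GRanges(chrV, IRanges(pos, width = 1L), strand = strandV,
                  seqinfo = genome)
    new("TagLibrary", tags = sort(gr, ignore.strand = TRUE),
        replicateId = "secondary", condition = "fasted",
        deduplicated = FALSE)
}

#' Simulate a complete study
#'
#' One call producing every mutually consistent artifact: genome
#' sequence, transcriptome, 5 + 5 replicate tag libraries, secondary
#' factor library, DE table and ground truth.
#'
#' @param config a [SimulationConfig].
#' @return named list: `genome`, `sequence`, `transcriptome`, `libs`
#'   (list fasted/refed of TagLibrary lists), `secondary`, `deTable`,
#'   `truth`.
#' @export
simulateStudy <- function(config = simulationConfig()) {
    layout <- .layoutStudy(config)
    sequence <- .buildSequence(layout, config)
    set.seed(config@seed + 2L)
    libs <- lapply(CONDITIONS, function(cond)
        lapply(seq_len(config@nReplicates), function(r)
            .emitLibrary(layout, config, cond, r, TRUE)))
    names(libs) <- CONDITIONS
    secondary <- .secondaryFromLayout(layout, config)
    truth <- new("TruthSet", sites = layout$sites, genes = layout$genes,
                 config = config)
    g <- layout$genes
    deTable <- data.frame(gene = g$gene, log2fc = g$log2fc,
                          direction = g$de, measured = g$measured,
                          stringsAsFactors = FALSE)
    list(genome = layout$genome, sequence = sequence,
         transcriptome = transcriptomeFromTable(layout$geneTab,
                                                layout$genome),
         libs = libs, secondary = secondary,
         deTable = deTable, truth = truth)
}

#' Write a simulated study to disk in standard formats
#'
#' Emits genome.fa, chrom.sizes, genes.txt (refFlat-like),
#' rep{i}_{condition}.tagAlign, secondary.tagAlign, de_genes.tsv and
#' truth tables (truth_sites.tsv, truth_genes.tsv). Every planted
#' object is recoverable from these files alone.
#'
#' @param study list from [simulateStudy()].
#' @param outdir output directory (created).
#' @return invisibly, the vector of written paths.
#' @export
writeStudy <- function(study, outdir) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(
        genome = file.path(outdir, "genome.fa"),
        sizes = file.path(outdir, "chrom.sizes"),
        genes = file.path(outdir, "genes.txt"),
        de = file.path(outdir, "de_genes.tsv"))
    writeGenomeFasta(study$sequence, paths["genome"])
    writeChromSizes(study$genome, paths["sizes"])
    writeGeneTable(study$transcriptome, paths["genes"])
    writeDeTable(study$deTable, paths["de"])
    for (cond in names(study$libs))
        for (lib in study$libs[[cond]]) {
            f <- file.path(outdir, sprintf("%s_%s.tagAlign",
                                           replicateId(lib), cond))
            writeTagAlign(lib, f)
            paths <- c(paths, f)
        }
    f <- file.path(outdir, "secondary.tagAlign")
    writeTagAlign(study$secondary, f)
    paths <- c(paths, f)
    s <- truthSites(study$truth)
    writeTsv(data.frame(chrom = as.character(seqnames(s)),
                        pos = start(s), as.data.frame(mcols(s))),
             file.path(outdir, "truth_sites.tsv"))
    writeTsv(as.data.frame(truthGenes(study$truth)),
             file.path(outdir, "truth_genes.tsv"))
    paths <- c(paths, file.path(outdir, c("truth_sites.tsv",
                                          "truth_genes.tsv")))
    invisible(unname(paths))
}
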