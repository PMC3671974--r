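#' @import methods
#' @import BiocGenerics
#' @import S4Vectors
#' @import IRanges
#' @import GenomicRanges
#' @import GenomeInfoDb
NULL

#' TagLibrary: stranded 5'-end read positions for one replicate or pool
#'
#' Holds the 5'-end coordinates of sequenced ChIP tags as a width-1
#' \linkS4class{GRanges} (one range per tag, strand mandatory), together
#' with the replicate and condition labels. After [dedupeTags()] the
#' ranges are unique on (chromosome, position, strand); pooled libraries
#' built with [poolLibraries()] are multisets and may contain the same
#' position several times, mirroring the pooling of non-redundant
#' per-replicate read sets.
#'
#' @slot tags width-1 `GRanges` of 5'-end positions with strand.
#' @slot replicateId character(1) replicate (or pool) label.
#' @slot condition character(1) condition label (e.g. "fasted").
#' @slot deduplicated logical(1); `TRUE` when the library is guaranteed
#'   unique on (chrom, pos, strand).
#'
#' @seealso [dedupeTags()], [poolLibraries()], [readTagAlign()]
#' @export
setClass("TagLibrary",
    representation(
        tags = "GRanges",
        replicateId = "character",
        condition = "character",
        deduplicated = "logical"
    ),
    prototype(replicateId = NA_character_, condition = NA_character_,
              deduplicated = FALSE)
)

setValidity("TagLibrary", function(object) {
    gr <- object@tags
    if (length(gr) && any(width(gr) != 1L))
        return("tags must be width-1 ranges (5'-end positions)")
    if (length(gr) && any(strand(gr) == "*"))
        return("tags must be stranded (+ or -)")
    sl <- seqlengths(gr)
    if (length(gr) && !all(is.na(sl))) {
        lens <- sl[as.character(seqnames(gr))]
        bad <- which(!is.na(lens) & (start(gr) < 1L | start(gr) > lens))
        if (length(bad))
            return(sprintf("tag %d (%s:%d) outside chromosome bounds",
                           bad[1L], as.character(seqnames(gr))[bad[1L]],
                           start(gr)[bad[1L]]))
    }
    TRUE
})

#' PeakSet: non-overlapping called peaks from one pool
#'
#' Peaks are a sorted, within-set non-overlapping `GRanges` carrying the
#' metadata columns `summit` (coordinate of maximum fragment coverage),
#' `height_rpm` (maximum stack height in reads per million), `pvalue`
#' and `qvalue`.
#'
#' @slot peaks `GRanges` with mcols summit, height_rpm, pvalue, qvalue.
#' @slot source character(1) label (condition / pool identity).
#' @slot callerConfig list of caller parameters (see [callerConfig()]).
#' @export
setClass("PeakSet",
    representation(peaks = "GRanges", source = "character",
                   callerConfig = "list"),
    prototype(source = NA_character_, callerConfig = list())
)

setValidity("PeakSet", function(object) {
    gr <- object@peaks
    if (!length(gr)) return(TRUE)
    need <- c("summit", "height_rpm")
    if (!all(need %in% colnames(mcols(gr))))
        return("peaks need mcols 'summit' and 'height_rpm'")
    if (is.unsorted(order(as.integer(seqnames(gr)), start(gr))))
        return("peaks must be sorted by (chrom, start)")
    red <- reduce(gr, ignore.strand = TRUE)
    if (length(red) != length(gr))
        return("peaks within a set must be non-overlapping")
    s <- mcols(gr)$summit
    if (any(s < start(gr) | s > end(gr)))
        return("summit must lie inside its peak")
    if (any(mcols(gr)$height_rpm < 0))
        return("height_rpm must be >= 0")
    TRUE
})

#' SsiResult: outcome of the single-sample-independence filter
#'
#' Partition of a full-pool [PeakSet] into peaks retained (matched in
#' every leave-one-out pool) and removed, with two per-replicate removal
#' tallies: `removalUnique[r]` counts peaks whose only failing pool is
#' the one excluding replicate r, and `removalPerPool[r]` counts every
#' removed peak once per failing pool.
#'
#' @slot retained,removed [PeakSet] objects partitioning the input.
#' @slot removalUnique,removalPerPool named integer tallies.
#' @slot matchTable `DataFrame` with one row per full-pool peak: id,
#'   retained flag, per-pool match flags, attributed replicate(s).
#' @export
setClass("SsiResult",
    representation(retained = "PeakSet", removed = "PeakSet",
                   removalUnique = "integer", removalPerPool = "integer",
                   matchTable = "DataFrame")
)

#' Transcriptome: gene models with a TSS index
#'
#' @slot genes `GRanges` spanning each transcript body, with mcols
#'   `gene_symbol`, `transcript_id`, `tss`, `tes` (1-based genomic
#'   coordinates), `cds_start`, `cds_end` (NA for non-coding).
#' @slot exons `GRangesList` parallel to `genes`, exons sorted by
#'   genomic position.
#' @export
setClass("Transcriptome",
    representation(genes = "GRanges", exons = "GRangesList")
)

setValidity("Transcriptome", function(object) {
    g <- object@genes
    if (length(g) != length(object@exons))
        return("genes and exons must be parallel")
    need <- c("gene_symbol", "transcript_id", "tss", "tes")
    if (length(g) && !all(need %in% colnames(mcols(g))))
        return("genes need mcols gene_symbol, transcript_id, tss, tes")
    if (length(g)) {
        tss <- mcols(g)$tss
        plus <- as.character(strand(g)) == "+"
        ok <- ifelse(plus, tss == start(g), tss == end(g))
        if (!all(ok))
            return("tss must equal the strand-appropriate transcript end")
    }
    TRUE
})

#' PWM: position weight matrix with log-odds scores
#'
#' Counts are a 4 x width matrix (rows A, C, G, T); log-odds are
#' log2((count + pseudocount) / column total adjusted / background).
#'
#' @slot name character(1) motif name.
#' @slot counts 4 x width numeric count matrix, rownames A,C,G,T.
#' @slot logOdds 4 x width numeric log-odds matrix.
#' @slot pseudocount numeric(1) per-cell pseudocount used.
#' @slot background numeric(4) background base frequencies.
#' @export
setClass("PWM",
    representation(name = "character", counts = "matrix",
                   logOdds = "matrix", pseudocount = "numeric",
                   background = "numeric")
)

setValidity("PWM", function(object) {
    if (!identical(rownames(object@counts), c("A", "C", "G", "T")))
        return("counts rownames must be A, C, G, T")
    if (any(object@counts < 0)) return("counts must be non-negative")
    if (any(colSums(object@counts) <= 0))
        return("every position must have positive total count")
    if (!all(is.finite(object@logOdds)))
        return("log-odds must be finite (apply a pseudocount)")
    TRUE
})

#' SimulationConfig: study conditions for the synthetic-data generator
#'
#' Defaults encode the study design the pipeline assumes: 5 biological
#' replicates in each of two conditions, constitutive binding with a
#' weak global condition effect (median 1.3-fold), single-replicate
#' artifact peaks, a CRE motif mix at true sites, ~20% TATA-containing
#' promoters, and a differential-expression table at |fold change| >=
#' 1.5 with 60% of DE genes (vs 33% of background genes) bound.
#'
#' @slot nChroms,chromBp genome shape (default 2 x 1 Mb).
#' @slot nGenes number of genes (default 120; compact genes with wide
#'   inter-gene gaps so 10 kb target windows stay disjoint).
#' @slot fracTata fraction of promoters with a planted TATA box (0.20).
#' @slot nTrueSites,nArtifactSites numbers of true binding sites (200)
#'   and single-replicate artifact sites (20).
#' @slot nReplicates replicates per condition (5).
#' @slot enrichmentFold tag-density enrichment of true sites over
#'   background (5); `artifactFold` likewise for artifacts (15).
#' @slot globalFoldMedian median fasted/re-fed binding fold (1.3) and
#'   `foldLog2Sd` the spread of per-site log2 folds (0.25).
#' @slot fracDeGenes fraction of genes differentially expressed (0.15);
#'   `deFoldMin` minimum DE fold change (1.5); `fracMeasured` fraction
#'   of genes present on the expression platform (0.90).
#' @slot fracDeBound,fracBgBound fractions of DE (0.60) and non-DE
#'   (0.33) genes that receive a true binding site.
#' @slot depthPerReplicate emitted tags per replicate (1e5).
#' @slot fragmentBp mean sonication fragment length (108).
#' @slot motifMix length-3 fractions of true sites carrying a full CRE,
#'   a half CRE, or no CRE (0.5, 0.3, 0.2).
#' @slot minSiteSpacingBp minimum distance between planted sites (1000).
#' @slot seed integer seed; every artifact of a run is a pure function
#'   of (config, seed).
#' @export
setClass("SimulationConfig",
    representation(
        nChroms = "integer", chromBp = "integer", nGenes = "integer",
        fracTata = "numeric", nTrueSites = "integer",
        nArtifactSites = "integer", nReplicates = "integer",
        enrichmentFold = "numeric", artifactFold = "numeric",
        globalFoldMedian = "numeric", foldLog2Sd = "numeric",
        fracDeGenes = "numeric", deFoldMin = "numeric",
        fracMeasured = "numeric", fracDeBound = "numeric",
        fracBgBound = "numeric", depthPerReplicate = "integer",
        fragmentBp = "integer", motifMix = "numeric",
        minSiteSpacingBp = "integer", seed = "integer"
    ),
    prototype(
        nChroms = 2L, chromBp = 1000000L, nGenes = 120L,
        fracTata = 0.20, nTrueSites = 200L, nArtifactSites = 20L,
        nReplicates = 5L, enrichmentFold = 5, artifactFold = 15,
        globalFoldMedian = 1.3, foldLog2Sd = 0.25,
        fracDeGenes = 0.15, deFoldMin = 1.5, fracMeasured = 0.90,
        fracDeBound = 0.60, fracBgBound = 0.33,
        depthPerReplicate = 100000L, fragmentBp = 108L,
        motifMix = c(0.5, 0.3, 0.2), minSiteSpacingBp = 1000L,
        seed = 1L
    )
)

setValidity("SimulationConfig", function(object) {
    fr <- c(object@fracTata, object@fracDeGenes, object@fracMeasured,
            object@fracDeBound, object@fracBgBound, object@motifMix)
    if (any(fr < 0 | fr > 1)) return("all fractions must lie in [0, 1]")
    if (abs(sum(object@motifMix) - 1) > 1e-8)
        return("motifMix must sum to 1")
    if (object@depthPerReplicate <= 0L) return("depth must be positive")
    if (object@fragmentBp <= 0L) return("fragmentBp must be positive")
    if (object@minSiteSpacingBp < 2L * object@fragmentBp)
        return("minSiteSpacingBp must be >= 2 * fragmentBp")
    if (object@nReplicates < 2L)
        return("need >= 2 replicates per condition")
    TRUE
})

#' TruthSet: ground truth emitted alongside a simulated study
#'
#' @slot sites `GRanges` of planted sites (width 1 at the site center)
#'   with mcols `site_id`, `type` ("true"/"artifact"), `fold`
#'   (fasted/re-fed binding fold; NA for artifacts), `motif`
#'   ("full"/"half"/"none"), `owner_replicate` (artifacts only),
#'   `linked_gene` (symbol or NA).
#' @slot genes `DataFrame` with one row per gene: symbol, tss, strand,
#'   tata (planted flag), de ("up"/"down"/"none"), measured, bound.
#' @slot config the [SimulationConfig] that produced the study.
#' @export
setClass("TruthSet",
    representation(sites = "GRanges", genes = "DataFrame",
                   config = "SimulationConfig")
)
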