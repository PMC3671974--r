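# Readers and writers for the plain-text formats the pipeline touches.
# BED-family files are 0-based half-open on disk and shifted to the
# 1-based closed GRanges convention on read (and back on write).

#' @importFrom utils read.table write.table
NULL

#' Read a chrom.sizes table
#'
#' Two tab-separated columns (name, length), no header.
#' @param file path.
#' @return a `Seqinfo`.
#' @export
readChromSizes <- function(file) {
    d <- read.table(file, sep = "\t", header = FALSE,
                    col.names = c("chrom", "length"),
                    colClasses = c("character", "integer"))
    genomeIndex(stats::setNames(d$length, d$chrom))
}

#' Write a chrom.sizes table
#' @param genome a `Seqinfo`.
#' @param file path.
#' @export
writeChromSizes <- function(genome, file) {
    write.table(
        data.frame(chrom = GenomeInfoDb::seqnames(genome),
                   length = seqlengths(genome)),
        file, sep = "\t", quote = FALSE, row.names = FALSE,
        col.names = FALSE)
    invisible(file)
}

#' Read a tagAlign / BED6 tag file into a TagLibrary
#'
#' Columns: chrom, start (0-based), end, name, score, strand. The tag is
#' reduced to its 5'-end position: `start + 1` on the plus strand, `end`
#' on the minus strand (1-based).
#'
#' @param file path.
#' @param genome `Seqinfo` for bound checking.
#' @param replicateId,condition labels.
#' @param dedupe collapse redundant reads (default TRUE).
#' @return a [TagLibrary].
#' @export
readTagAlign <- function(file, genome, replicateId = basename(file),
                         condition = "cond", dedupe = TRUE) {
    d <- read.table(file, sep = "\t", header = FALSE,
                    colClasses = c("character", "integer", "integer",
                                   "character", "numeric", "character"))
    names(d) <- c("chrom", "start", "end", "name", "score", "strand")
    pos5 <- ifelse(d$strand == "-", d$end, d$start + 1L)
    gr <- GRanges(d$chrom, IRanges(pos5, width = 1L), strand = d$strand)
    if (dedupe) {
        dedupeTags(gr, genome, replicateId, condition)
    } else {
        gr <- .coerceTags(gr, genome)
        new("TagLibrary", tags = sort(gr, ignore.strand = TRUE),
            replicateId = replicateId, condition = condition,
            deduplicated = FALSE)
    }
}

#' Write a TagLibrary as tagAlign (BED6)
#'
#' Tags are written as `readLen`-bp reads anchored at their 5' end,
#' clipped to chromosome bounds; reading the file back recovers the
#' same 5'-end positions.
#'
#' @param lib a [TagLibrary].
#' @param file path.
#' @param readLen nominal read length in bp (default 36).
#' @export
writeTagAlign <- function(lib, file, readLen = 36L) {
    gr <- tags(lib)
    pos <- start(gr)
    minus <- as.character(strand(gr)) == "-"
    lens <- seqlengths(gr)[as.character(seqnames(gr))]
    s0 <- ifelse(minus, pmax(pos - readLen, 0L), pos - 1L)
    e <- ifelse(minus, pos, pmin(pos + readLen - 1L, lens))
    d <- data.frame(chrom = as.character(seqnames(gr)), start = s0, end = e,
                    name = "N", score = 0L,
                    strand = as.character(strand(gr)))
    write.table(d, file, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    invisible(file)
}

#' Write a PeakSet as BED6+4
#'
#' Columns: chrom, start (0-based), end, id, score (height in RPM x
#' 1000 rounded to integer), strand "."; then summit (1-based),
#' height_rpm, pvalue, qvalue. Rows sorted by (chrom, start, end);
#' floats carry 6 significant digits.
#'
#' @param peakSet a [PeakSet].
#' @param file path.
#' @export
writePeakBed <- function(peakSet, file) {
    gr <- peaks(peakSet)
    if (!length(gr)) {
        cat("", file = file)
        return(invisible(file))
    }
    m <- mcols(gr)
    d <- data.frame(
        chrom = as.character(seqnames(gr)), start = start(gr) - 1L,
        end = end(gr),
        id = if (!is.null(m$id)) m$id else sprintf("peak_%05d", seq_along(gr)),
        score = as.integer(round(m$height_rpm * 1000)), strand = ".",
        summit = m$summit, height_rpm = signif(m$height_rpm, 6),
        pvalue = signif(if (!is.null(m$pvalue)) m$pvalue else NA_real_, 6),
        qvalue = signif(if (!is.null(m$qvalue)) m$qvalue else NA_real_, 6))
    d <- d[order(d$chrom, d$start, d$end), , drop = FALSE]
    write.table(d, file, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    invisible(file)
}

#' Read a BED6+4 peak file written by [writePeakBed()]
#'
#' Plain BED3/BED6 region sets are also accepted (heights default to 0),
#' so externally called peaks can enter the SSI filter. Regions on
#' chromosomes absent from `genome` are skipped with a warning.
#'
#' @param file path.
#' @param genome `Seqinfo`.
#' @param source label for the resulting set.
#' @param callerConfig optional caller parameter list to attach.
#' @return a [PeakSet].
#' @export
readPeakBed <- function(file, genome, source = basename(file),
                        callerConfig = list()) {
    if (length(readLines(file, n = 1L)) == 0L)
        return(new("PeakSet", peaks = GRanges(seqinfo = genome),
                   source = source, callerConfig = callerConfig))
    d <- read.table(file, sep = "\t", header = FALSE,
                    colClasses = "character")
    unknown <- !(d[[1L]] %in% GenomeInfoDb::seqnames(genome))
    if (any(unknown)) {
        warning(sum(unknown), " region(s) on unknown chromosomes skipped")
        d <- d[!unknown, , drop = FALSE]
    }
    start1 <- as.integer(d[[2L]]) + 1L
    end1 <- as.integer(d[[3L]])
    gr <- GRanges(d[[1L]], IRanges(start1, end1), seqinfo = genome)
    mcols(gr)$id <- if (ncol(d) >= 4L) d[[4L]] else
        sprintf("peak_%05d", seq_along(gr))
    mcols(gr)$summit <- if (ncol(d) >= 7L) as.integer(d[[7L]]) else
        as.integer(floor((start1 + end1) / 2))
    mcols(gr)$height_rpm <- if (ncol(d) >= 8L) as.numeric(d[[8L]]) else 0
    mcols(gr)$pvalue <- if (ncol(d) >= 9L) as.numeric(d[[9L]]) else NA_real_
    mcols(gr)$qvalue <- if (ncol(d) >= 10L) as.numeric(d[[10L]]) else NA_real_
    o <- order(as.integer(seqnames(gr)), start(gr), end(gr))
    new("PeakSet", peaks = gr[o], source = source,
        callerConfig = callerConfig)
}

#' Read a refFlat-like gene table into a Transcriptome
#'
#' Tab-separated, no header, columns: geneName, transcriptId, chrom,
#' strand, txStart (0-based), txEnd, cdsStart (0-based), cdsEnd,
#' exonCount, exonStarts (comma list, 0-based), exonEnds. Non-coding
#' transcripts have cdsStart == cdsEnd. Genes on chromosomes absent
#' from `genome` are skipped with a warning.
#'
#' @param file path.
#' @param genome `Seqinfo`.
#' @return a [Transcriptome].
#' @export
readGeneTable <- function(file, genome) {
    d <- read.table(file, sep = "\t", header = FALSE,
                    colClasses = c("character", "character", "character",
                                   "character", rep("integer", 4L),
                                   "integer", "character", "character"))
    names(d) <- c("gene", "tx", "chrom", "strand", "txStart", "txEnd",
                  "cdsStart", "cdsEnd", "exonCount", "exonStarts",
                  "exonEnds")
    unknown <- !(d$chrom %in% GenomeInfoDb::seqnames(genome))
    if (any(unknown)) {
        warning(sum(unknown), " gene(s) on unknown chromosomes skipped")
        d <- d[!unknown, , drop = FALSE]
    }
    transcriptomeFromTable(d, genome)
}

# build a Transcriptome from a parsed refFlat data.frame
transcriptomeFromTable <- function(d, genome) {
    for (col in c("txStart", "txEnd", "cdsStart", "cdsEnd"))
        d[[col]] <- as.integer(d[[col]])
    g <- GRanges(d$chrom, IRanges(d$txStart + 1L, d$txEnd),
                 strand = d$strand, seqinfo = genome)
    noncoding <- d$cdsStart == d$cdsEnd
    mcols(g) <- DataFrame(
        gene_symbol = d$gene, transcript_id = d$tx,
        tss = ifelse(d$strand == "-", d$txEnd, d$txStart + 1L),
        tes = ifelse(d$strand == "-", d$txStart + 1L, d$txEnd),
        cds_start = ifelse(noncoding, NA_integer_, d$cdsStart + 1L),
        cds_end = ifelse(noncoding, NA_integer_, d$cdsEnd))
    exons <- GRangesList(lapply(seq_len(nrow(d)), function(i) {
        es <- as.integer(strsplit(d$exonStarts[i], ",")[[1L]]) + 1L
        ee <- as.integer(strsplit(d$exonEnds[i], ",")[[1L]])
        sort(GRanges(d$chrom[i], IRanges(es, ee), strand = d$strand[i],
                     seqinfo = genome))
    }))
    new("Transcriptome", genes = g, exons = exons)
}

#' Write a Transcriptome as a refFlat-like gene table
#' @param transcriptome a [Transcriptome].
#' @param file path.
#' @export
writeGeneTable <- function(transcriptome, file) {
    g <- genes(transcriptome)
    ex <- exonsOf(transcriptome)
    m <- mcols(g)
    d <- data.frame(
        gene = m$gene_symbol, tx = m$transcript_id,
        chrom = as.character(seqnames(g)),
        strand = as.character(strand(g)),
        txStart = start(g) - 1L, txEnd = end(g),
        cdsStart = ifelse(is.na(m$cds_start), start(g) - 1L,
                          m$cds_start - 1L),
        cdsEnd = ifelse(is.na(m$cds_end),
                        ifelse(is.na(m$cds_start), start(g) - 1L, NA),
                        m$cds_end),
        exonCount = lengths(ex),
        exonStarts = vapply(ex, function(e)
            paste0(paste(start(e) - 1L, collapse = ","), ","), character(1)),
        exonEnds = vapply(ex, function(e)
            paste0(paste(end(e), collapse = ","), ","), character(1)))
    write.table(d, file, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    invisible(file)
}

#' Read a differential-expression gene table
#'
#' Tab-separated with header; columns `gene`, `log2fc`, `direction`
#' (up/down/none), `measured` (0/1). The calling thresholds (here 10%
#' FDR, |fold change| >= 1.5 upstream) are the producer's business;
#' this table is consumed as-is.
#'
#' @param file path.
#' @return data.frame with those four columns.
#' @export
readDeTable <- function(file) {
    d <- read.table(file, sep = "\t", header = TRUE,
                    colClasses = c("character", "numeric", "character",
                                   "integer"))
    need <- c("gene", "log2fc", "direction", "measured")
    if (!all(need %in% names(d)))
        stop("DE table must have header columns: ",
             paste(need, collapse = ", "))
    bad <- !(d$direction %in% c("up", "down", "none"))
    if (any(bad)) stop("direction must be up/down/none")
    inconsistent <- (d$direction == "up" & d$log2fc < 0) |
        (d$direction == "down" & d$log2fc > 0)
    if (any(inconsistent))
        warning(sum(inconsistent), " DE rows with direction/log2fc mismatch")
    d
}

#' Write a differential-expression gene table
#' @param deTable data.frame as from [readDeTable()].
#' @param file path.
#' @export
writeDeTable <- function(deTable, file) {
    d <- deTable
    d$log2fc <- signif(d$log2fc, 6)
    write.table(d, file, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(file)
}

#' Read a JASPAR-style position count matrix
#'
#' Accepts the common text renderings: an optional `>name` header line
#' followed by four rows for A, C, G, T, with counts optionally wrapped
#' in `[ ]` and an optional leading base letter.
#'
#' @param file path.
#' @param pseudocount per-cell pseudocount for the log-odds (default 0.5).
#' @param background background base frequencies (default uniform 0.25).
#' @return a [PWM].
#' @export
readJasparPwm <- function(file, pseudocount = 0.5,
                          background = rep(0.25, 4L)) {
    lines <- readLines(file)
    lines <- lines[nzchar(trimws(lines))]
    name <- "motif"
    if (startsWith(lines[1L], ">")) {
        name <- trimws(sub("^>\\s*", "", lines[1L]))
        lines <- lines[-1L]
    }
    if (length(lines) < 4L) stop("expected 4 count rows (A, C, G, T)")
    rows <- lapply(lines[1:4], function(l) {
        l <- gsub("[][]", " ", l)
        l <- sub("^\\s*[ACGTacgt][:]?\\s+", "", l)
        as.numeric(strsplit(trimws(l), "\\s+")[[1L]])
    })
    if (length(unique(lengths(rows))) != 1L)
        stop("count rows have unequal widths")
    counts <- do.call(rbind, rows)
    rownames(counts) <- c("A", "C", "G", "T")
    newPWM(name, counts, pseudocount = pseudocount,
           background = background)
}

#' Write TSV summary tables with a deterministic contract
#'
#' Header row; floats rendered with 6 significant digits; rows written
#' in the order given (callers sort by chrom, start, end).
#'
#' @param d data.frame.
#' @param file path.
#' @export
writeTsv <- function(d, file) {
    num <- vapply(d, is.double, logical(1))
    d[num] <- lapply(d[num], signif, digits = 6)
    write.table(d, file, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(file)
}

#' Read a genome FASTA
#'
#' @param file path (uncompressed FASTA).
#' @return a named `DNAStringSet`.
#' @export
readGenomeFasta <- function(file) {
    seqs <- Biostrings::readDNAStringSet(file)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    seqs
}

#' Write a genome FASTA
#' @param seqs named `DNAStringSet`.
#' @param file path.
#' @export
writeGenomeFasta <- function(seqs, file) {
    Biostrings::writeXStringSet(seqs, file, width = 70L)
    invisible(file)
}
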