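# Accessor generics. Slot access from user code goes through these.

#' @rdname TagLibrary-class
#' @param object,x a TagLibrary (or other class as documented)
#' @export
setGeneric("tags", function(object) standardGeneric("tags"))
#' @rdname TagLibrary-class
#' @export
setMethod("tags", "TagLibrary", function(object) object@tags)

#' @rdname TagLibrary-class
#' @export
setGeneric("nTags", function(object) standardGeneric("nTags"))
#' @rdname TagLibrary-class
#' @export
setMethod("nTags", "TagLibrary", function(object) length(object@tags))

#' @rdname TagLibrary-class
#' @export
setGeneric("replicateId", function(object) standardGeneric("replicateId"))
#' @rdname TagLibrary-class
#' @export
setMethod("replicateId", "TagLibrary", function(object) object@replicateId)

#' @rdname TagLibrary-class
#' @export
setGeneric("condition", function(object) standardGeneric("condition"))
#' @rdname TagLibrary-class
#' @export
setMethod("condition", "TagLibrary", function(object) object@condition)

setMethod("show", "TagLibrary", function(object) {
    cat(sprintf("TagLibrary '%s' (%s): %d tags%s\n",
        object@replicateId, object@condition, nTags(object),
        if (object@deduplicated) ", deduplicated" else ""))
})

#' @rdname PeakSet-class
#' @param object a PeakSet
#' @export
setGeneric("peaks", function(object) standardGeneric("peaks"))
#' @rdname PeakSet-class
#' @export
setMethod("peaks", "PeakSet", function(object) object@peaks)

#' @rdname PeakSet-class
#' @export
setGeneric("peakSource", function(object) standardGeneric("peakSource"))
#' @rdname PeakSet-class
#' @export
setMethod("peakSource", "PeakSet", function(object) object@source)

#' @rdname PeakSet-class
#' @export
setGeneric("callerConfigOf", function(object) standardGeneric("callerConfigOf"))
#' @rdname PeakSet-class
#' @export
setMethod("callerConfigOf", "PeakSet", function(object) object@callerConfig)

setMethod("length", "PeakSet", function(x) length(x@peaks))

setMethod("show", "PeakSet", function(object) {
    cat(sprintf("PeakSet '%s': %d peaks\n", object@source, length(object)))
    if (length(object)) {
        h <- mcols(object@peaks)$height_rpm
        cat(sprintf("  height_rpm: median %.3g, max %.3g\n",
                    stats::median(h), max(h)))
    }
})

#' @rdname SsiResult-class
#' @param object an SsiResult
#' @export
setGeneric("retained", function(object) standardGeneric("retained"))
#' @rdname SsiResult-class
#' @export
setMethod("retained", "SsiResult", function(object) object@retained)

#' @rdname SsiResult-class
#' @export
setGeneric("removed", function(object) standardGeneric("removed"))
#' @rdname SsiResult-class
#' @export
setMethod("removed", "SsiResult", function(object) object@removed)

#' @rdname SsiResult-class
#' @export
setGeneric("removalByReplicate",
           function(object) standardGeneric("removalByReplicate"))
#' @rdname SsiResult-class
#' @export
setMethod("removalByReplicate", "SsiResult", function(object)
    list(unique_failure = object@removalUnique,
         per_failing_pool = object@removalPerPool))

#' @rdname SsiResult-class
#' @export
setGeneric("matchTable", function(object) standardGeneric("matchTable"))
#' @rdname SsiResult-class
#' @export
setMethod("matchTable", "SsiResult", function(object) object@matchTable)

setMethod("show", "SsiResult", function(object) {
    cat(sprintf("SsiResult: %d retained, %d removed\n",
                length(object@retained), length(object@removed)))
})

#' @rdname Transcriptome-class
#' @param object a Transcriptome
#' @export
setGeneric("genes", function(object) standardGeneric("genes"))
#' @rdname Transcriptome-class
#' @export
setMethod("genes", "Transcriptome", function(object) object@genes)

#' @rdname Transcriptome-class
#' @export
setGeneric("exonsOf", function(object) standardGeneric("exonsOf"))
#' @rdname Transcriptome-class
#' @export
setMethod("exonsOf", "Transcriptome", function(object) object@exons)

setMethod("length", "Transcriptome", function(x) length(x@genes))

setMethod("show", "Transcriptome", function(object) {
    cat(sprintf("Transcriptome: %d transcripts on %d sequence(s)\n",
                length(object),
                length(unique(as.character(seqnames(object@genes))))))
})

setMethod("show", "PWM", function(object) {
    cat(sprintf("PWM '%s', width %d, consensus %s\n", object@name,
                ncol(object@counts), pwmConsensus(object)))
})

setMethod("show", "SimulationConfig", function(object) {
    cat(sprintf(paste0(
        "SimulationConfig: %d x %.3g bp genome, %d genes, ",
        "%d true + %d artifact sites, %d+%d replicates, ",
        "%g tags/replicate, median fold %.2f, seed %d\n"),
        object@nChroms, as.numeric(object@chromBp), object@nGenes,
        object@nTrueSites, object@nArtifactSites,
        object@nReplicates, object@nReplicates,
        as.numeric(object@depthPerReplicate),
        object@globalFoldMedian, object@seed))
})

#' @rdname TruthSet-class
#' @param object a TruthSet
#' @export
setGeneric("truthSites", function(object) standardGeneric("truthSites"))
#' @rdname TruthSet-class
#' @export
setMethod("truthSites", "TruthSet", function(object) object@sites)

#' @rdname TruthSet-class
#' @export
setGeneric("truthGenes", function(object) standardGeneric("truthGenes"))
#' @rdname TruthSet-class
#' @export
setMethod("truthGenes", "TruthSet", function(object) object@genes)

setMethod("show", "TruthSet", function(object) {
    tt <- table(mcols(object@sites)$type)
    cat(sprintf("TruthSet: %d true sites, %d artifacts, %d genes\n",
                as.integer(tt["true"]),
                if ("artifact" %in% names(tt)) as.integer(tt["artifact"]) else 0L,
                nrow(object@genes)))
})
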