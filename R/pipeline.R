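# One-shot pipeline orchestration: simulate -> callpeaks (full + LOO)
# -> ssi -> quantify -> diff -> motifs -> annotate -> integrate ->
# profile. Stages communicate through files in the output directory so
# a run is reproducible and resumable from its manifest.

#' Pipeline configuration
#'
#' @param outdir output directory.
#' @param sim a [SimulationConfig] (the simulate stage writes its
#'   files; pass `NULL` to run on pre-existing files in `outdir/sim`).
#' @param caller a [callerConfig()] list.
#' @param heightThreshold consolidated-region average-height cutoff in
#'   RPM (default 0.35).
#' @param diffFdr differential-binding FDR (default 0.10).
#' @param match SSI match rule, "overlap" or "summit".
#' @param featureMode feature priority for [classifySite()].
#' @param tataThreshold,tataWindowBp TATA call parameters (6, 250).
#' @param upstreamBp target-gene upstream window (10,000).
#' @param profileFlankBp,profileBinBp co-localization profile shape
#'   (2000, 25).
#' @param seed integer seed for the simulate stage.
#' @return named list.
#' @export
pipelineConfig <- function(outdir, sim = simulationConfig(),
                           caller = callerConfig(),
                           heightThreshold = 0.35, diffFdr = 0.10,
                           match = "overlap", featureMode = "default",
                           tataThreshold = 6, tataWindowBp = 250L,
                           upstreamBp = 10000L, profileFlankBp = 2000L,
                           profileBinBp = 25L, seed = 1L) {
    stopifnot(heightThreshold >= 0, diffFdr > 0, diffFdr < 1)
    if (!is.null(sim)) sim@seed <- as.integer(seed)
    list(outdir = outdir, sim = sim, caller = caller,
         heightThreshold = heightThreshold, diffFdr = diffFdr,
         match = match, featureMode = featureMode,
         tataThreshold = tataThreshold,
         tataWindowBp = as.integer(tataWindowBp),
         upstreamBp = as.integer(upstreamBp),
         profileFlankBp = as.integer(profileFlankBp),
         profileBinBp = as.integer(profileBinBp),
         seed = as.integer(seed))
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the [pipelineConfig()] arguments; `sim` and
#' `caller` are nested maps of [simulationConfig()] /
#' [callerConfig()] arguments.
#'
#' @param file YAML path.
#' @param outdir override for the output directory (optional).
#' @return a [pipelineConfig()] list.
#' @export
readPipelineConfig <- function(file, outdir = NULL) {
    y <- yaml::read_yaml(file)
    sim <- if (!is.null(y$sim)) do.call(simulationConfig, y$sim) else
        simulationConfig()
    caller <- if (!is.null(y$caller)) do.call(callerConfig, y$caller)
        else callerConfig()
    args <- y[setdiff(names(y), c("sim", "caller"))]
    if (!is.null(outdir)) args$outdir <- outdir
    if (is.null(args$outdir)) stop("config must name an outdir")
    do.call(pipelineConfig, c(args, list(sim = sim, caller = caller)))
}

.stageLog <- function(stage, ...) {
    message(format(Sys.time(), "[%Y-%m-%d %H:%M:%S] "), "[", stage,
            "] ", ...)
}

.md5 <- function(paths) unname(tools::md5sum(paths))

#' Run the full pipeline
#'
#' Stages run in dependency order; a stage failure aborts with the
#' stage named. The returned manifest (also written to
#' `outdir/manifest.tsv`) records per stage the outputs, their md5
#' checksums and the governing parameters; two runs with the same
#' configuration and seed produce identical checksums. With
#' `resume = TRUE`, stages whose recorded outputs all exist with
#' matching checksums are skipped. If the DE table is absent the
#' integrate stage is skipped with an explicit notice.
#'
#' @param config a [pipelineConfig()] list.
#' @param resume skip completed stages by checksum (default FALSE).
#' @return data.frame manifest (invisibly written as TSV too).
#' @export
runPipeline <- function(config, resume = FALSE) {
    outdir <- config$outdir
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    simdir <- file.path(outdir, "sim")
    manifestPath <- file.path(outdir, "manifest.tsv")
    prev <- if (resume && file.exists(manifestPath))
        utils::read.table(manifestPath, sep = "\t", header = TRUE,
                          colClasses = "character") else NULL
    manifest <- list()
    stageDone <- function(stage, outputs, params = "") {
        manifest[[stage]] <<- data.frame(
            stage = stage, status = "done",
            outputs = paste(basename(outputs), collapse = ";"),
            md5 = paste(.md5(outputs), collapse = ";"),
            params = params, stringsAsFactors = FALSE)
    }
    stageSkipped <- function(stage, why) {
        .stageLog(stage, "skipped: ", why)
        manifest[[stage]] <<- data.frame(
            stage = stage, status = "skipped", outputs = "", md5 = "",
            params = why, stringsAsFactors = FALSE)
    }
    canResume <- function(stage) {
        if (is.null(prev)) return(FALSE)
        row <- prev[prev$stage == stage & prev$status == "done", ]
        if (nrow(row) != 1L || !nzchar(row$outputs)) return(FALSE)
        files <- file.path(if (stage == "simulate") simdir else outdir,
                           strsplit(row$outputs, ";")[[1L]])
        all(file.exists(files)) &&
            identical(paste(.md5(files), collapse = ";"), row$md5)
    }
    fail <- function(stage, e) stop("pipeline stage '", stage,
                                    "' failed: ", conditionMessage(e),
                                    call. = FALSE)

    # ---- stage 1: simulate ----
    stage <- "simulate"
    if (canResume(stage)) {
        stageSkipped(stage, "resume: outputs up to date")
        manifest[[stage]]$status <- "done"
        manifest[[stage]]$outputs <- prev[prev$stage == stage, "outputs"]
        manifest[[stage]]$md5 <- prev[prev$stage == stage, "md5"]
    } else if (is.null(config$sim)) {
        need <- file.path(simdir, c("genome.fa", "chrom.sizes",
                                    "genes.txt"))
        if (!all(file.exists(need)))
            stop("no SimulationConfig and missing input file(s): ",
                 paste(need[!file.exists(need)], collapse = ", "))
        stageSkipped(stage, "external inputs supplied")
    } else tryCatch({
        .stageLog(stage, "seed=", config$sim@seed)
        paths <- writeStudy(simulateStudy(config$sim), simdir)
        stageDone(stage, paths, sprintf("seed=%d", config$sim@seed))
    }, error = function(e) fail(stage, e))

    genome <- readChromSizes(file.path(simdir, "chrom.sizes"))
    nrep <- if (!is.null(config$sim)) config$sim@nReplicates else
        length(list.files(simdir, "^rep[0-9]+_fasted\\.tagAlign$"))
    readLibs <- function(cond) lapply(seq_len(nrep), function(r)
        readTagAlign(file.path(simdir,
                               sprintf("rep%d_%s.tagAlign", r, cond)),
                     genome, sprintf("rep%d", r), cond))

    # ---- stage 2: callpeaks (full pool + every leave-one-out pool) ----
    stage <- "callpeaks"
    peakFiles <- unlist(lapply(CONDITIONS, function(cond) c(
        file.path(outdir, sprintf("peaks_%s_full.bed", cond)),
        file.path(outdir, sprintf("peaks_%s_loo_rep%d.bed", cond,
                                  seq_len(nrep))))))
    if (canResume(stage)) {
        stageSkipped(stage, "resume: outputs up to date")
        manifest[[stage]]$status <- "done"
        manifest[[stage]]$outputs <- prev[prev$stage == stage, "outputs"]
        manifest[[stage]]$md5 <- prev[prev$stage == stage, "md5"]
    } else tryCatch({
        .stageLog(stage, sprintf("fdr=%g fragment=%d window=%d",
                                 config$caller$fdr,
                                 config$caller$fragment_bp,
                                 config$caller$window_bp))
        for (cond in CONDITIONS) {
            libs <- readLibs(cond)
            full <- callPeaks(poolLibraries(libs), genome,
                              config$caller,
                              source = paste0(cond, "_full"))
            writePeakBed(full, file.path(outdir,
                sprintf("peaks_%s_full.bed", cond)))
            loo <- makeLooPools(libs)
            for (r in seq_along(loo)) {
                ps <- callPeaks(loo[[r]], genome, config$caller,
                                source = sprintf("%s_loo_rep%d",
                                                 cond, r))
                writePeakBed(ps, file.path(outdir,
                    sprintf("peaks_%s_loo_rep%d.bed", cond, r)))
            }
        }
        stageDone(stage, peakFiles,
                  sprintf("fdr=%g", config$caller$fdr))
    }, error = function(e) fail(stage, e))

    # ---- stage 3: ssi ----
    stage <- "ssi"
    ssiFiles <- unlist(lapply(CONDITIONS, function(cond)
        file.path(outdir, c(sprintf("retained_%s.bed", cond),
                            sprintf("ssi_report_%s.tsv", cond)))))
    tryCatch({
        .stageLog(stage, "match=", config$match)
        for (cond in CONDITIONS) {
            full <- readPeakBed(file.path(outdir,
                sprintf("peaks_%s_full.bed", cond)), genome,
                source = paste0(cond, "_full"),
                callerConfig = config$caller)
            loo <- lapply(seq_len(nrep), function(r)
                readPeakBed(file.path(outdir,
                    sprintf("peaks_%s_loo_rep%d.bed", cond, r)), genome,
                    source = sprintf("%s_loo_rep%d", cond, r),
                    callerConfig = config$caller))
            names(loo) <- sprintf("rep%d", seq_len(nrep))
            res <- ssiFilter(full, loo, match = config$match)
            writePeakBed(retained(res), file.path(outdir,
                sprintf("retained_%s.bed", cond)))
            writeTsv(as.data.frame(matchTable(res)), file.path(outdir,
                sprintf("ssi_report_%s.tsv", cond)))
        }
        stageDone(stage, ssiFiles, sprintf("match=%s", config$match))
    }, error = function(e) fail(stage, e))

    # ---- stage 4: quantify ----
    stage <- "quantify"
    regionsPath <- file.path(outdir, "regions.tsv")
    libSizesPath <- file.path(outdir, "lib_sizes.tsv")
    se <- tryCatch({
        .stageLog(stage, sprintf("min-height=%g RPM fragment=%d",
                                 config$heightThreshold,
                                 config$caller$fragment_bp))
        libs <- c(readLibs(CONDITIONS[1L]), readLibs(CONDITIONS[2L]))
        setA <- readPeakBed(file.path(outdir, sprintf("retained_%s.bed",
            CONDITIONS[1L])), genome, source = CONDITIONS[1L])
        setB <- readPeakBed(file.path(outdir, sprintf("retained_%s.bed",
            CONDITIONS[2L])), genome, source = CONDITIONS[2L])
        se <- mergeConditionPeaks(setA, setB, libs,
                                  config$heightThreshold,
                                  config$caller$fragment_bp)
        .writeRegionsTsv(se, regionsPath)
        writeTsv(as.data.frame(SummarizedExperiment::colData(se)),
                 libSizesPath)
        stageDone(stage, c(regionsPath, libSizesPath),
                  sprintf("min_height=%g", config$heightThreshold))
        se
    }, error = function(e) fail(stage, e))

    # ---- stage 5: diff ----
    stage <- "diff"
    diffPath <- file.path(outdir, "differential.tsv")
    tryCatch({
        .stageLog(stage, "fdr=", config$diffFdr)
        dr <- differentialBinding(se, config$diffFdr)
        writeTsv(as.data.frame(dr), diffPath)
        stageDone(stage, diffPath, sprintf("fdr=%g", config$diffFdr))
    }, error = function(e) fail(stage, e))

    genomeSeq <- readGenomeFasta(file.path(simdir, "genome.fa"))
    transcriptome <- readGeneTable(file.path(simdir, "genes.txt"),
                                   genome)
    regionsGr <- SummarizedExperiment::rowRanges(se)
    mcols(regionsGr)$id <- SummarizedExperiment::rowData(se)$id

    # ---- stage 6: motifs (CRE classes + TATA promoter flags) ----
    stage <- "motifs"
    motifPath <- file.path(outdir, "motif_classes.tsv")
    tataPath <- file.path(outdir, "tata_flags.tsv")
    tryCatch({
        .stageLog(stage, sprintf("tata score>=%g within %d bp",
                                 config$tataThreshold,
                                 config$tataWindowBp))
        cls <- classifyCre(centerWindows(regionsGr, genomeSeq, 100L))
        writeTsv(data.frame(id = mcols(regionsGr)$id,
                            cre_class = as.character(cls)), motifPath)
        pwm <- readJasparPwm(system.file("extdata",
            "tata_synthetic.jaspar", package = "ssiCistrome"))
        tata <- classifyTata(transcriptome, genomeSeq, pwm,
                             config$tataThreshold, config$tataWindowBp)
        writeTsv(data.frame(
            gene = mcols(genes(transcriptome))$gene_symbol,
            tata = as.integer(tata)), tataPath)
        stageDone(stage, c(motifPath, tataPath),
                  sprintf("tata_threshold=%g", config$tataThreshold))
    }, error = function(e) fail(stage, e))

    # ---- stage 7: annotate ----
    stage <- "annotate"
    annotPath <- file.path(outdir, "annotated.tsv")
    linksPath <- file.path(outdir, "target_links.tsv")
    targets <- tryCatch({
        .stageLog(stage, "feature priority=", config$featureMode)
        ann <- classifySite(regionsGr, transcriptome,
                            mode = config$featureMode)
        writeTsv(data.frame(id = mcols(regionsGr)$id,
                            as.data.frame(ann)), annotPath)
        targets <- mapTargets(regionsGr, transcriptome,
                              config$upstreamBp)
        writeTsv(targets$links, linksPath)
        stageDone(stage, c(annotPath, linksPath),
                  sprintf("upstream=%d", config$upstreamBp))
        targets
    }, error = function(e) fail(stage, e))

    # ---- stage 8: integrate ----
    stage <- "integrate"
    dePath <- file.path(simdir, "de_genes.tsv")
    groupsPath <- file.path(outdir, "groups.tsv")
    groups <- NULL
    if (!file.exists(dePath)) {
        stageSkipped(stage, "DE table absent: integrate stage skipped")
    } else tryCatch({
        .stageLog(stage, "DE table: ", dePath)
        deTable <- readDeTable(dePath)
        reg <- assignRegulationGroups(mcols(regionsGr)$id,
                                      targets$links, deTable)
        groups <- reg$groups
        writeTsv(data.frame(id = mcols(regionsGr)$id,
                            group = as.character(groups)), groupsPath)
        enr <- geneLevelEnrichment(deTable, targets$sitesPerGene)
        writeTsv(enr, file.path(outdir, "enrichment.tsv"))
        tataDf <- utils::read.table(tataPath, header = TRUE, sep = "\t")
        ct <- crosstabTataCreb(deTable,
            stats::setNames(tataDf$tata == 1L, tataDf$gene),
            stats::setNames(targets$sitesPerGene >= 1L,
                            names(targets$sitesPerGene)))
        writeTsv(ct, file.path(outdir, "crosstab.tsv"))
        stageDone(stage, c(groupsPath,
                           file.path(outdir, c("enrichment.tsv",
                                               "crosstab.tsv"))),
                  sprintf("n_conflicts=%d", reg$n_conflicts))
    }, error = function(e) fail(stage, e))

    # ---- stage 9: profile ----
    stage <- "profile"
    secPath <- file.path(simdir, "secondary.tagAlign")
    if (is.null(groups) || !file.exists(secPath)) {
        stageSkipped(stage, "regulation groups or secondary signal absent")
    } else tryCatch({
        .stageLog(stage, sprintf("flank=%d bin=%d",
                                 config$profileFlankBp,
                                 config$profileBinBp))
        sec <- readTagAlign(secPath, genome, "secondary", "fasted")
        prof <- averageProfile(regionsGr, groups, sec,
                               config$profileFlankBp,
                               config$profileBinBp,
                               config$caller$fragment_bp)
        pd <- data.frame(group = rep(rownames(prof$profiles),
                                     each = length(prof$offsets)),
                         offset = rep(prof$offsets,
                                      nrow(prof$profiles)),
                         mean_rpm = as.vector(t(prof$profiles)))
        writeTsv(pd, file.path(outdir, "profiles.tsv"))
        writeTsv(cbind(id = mcols(regionsGr)$id, prof$anchor_heights),
                 file.path(outdir, "anchor_heights.tsv"))
        stageDone(stage, file.path(outdir, c("profiles.tsv",
                                             "anchor_heights.tsv")),
                  sprintf("flank=%d", config$profileFlankBp))
    }, error = function(e) fail(stage, e))

    man <- do.call(rbind, manifest[c("simulate", "callpeaks", "ssi",
                                     "quantify", "diff", "motifs",
                                     "annotate", "integrate",
                                     "profile")])
    rownames(man) <- NULL
    utils::write.table(man, manifestPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(man)
}

# regions.tsv: one row per consolidated region, 1-based coordinates,
# per-replicate heights and counts, condition summaries, quartile
.writeRegionsTsv <- function(se, file) {
    gr <- SummarizedExperiment::rowRanges(se)
    rd <- SummarizedExperiment::rowData(se)
    H <- SummarizedExperiment::assay(se, "height_rpm")
    C <- SummarizedExperiment::assay(se, "count")
    d <- data.frame(chrom = as.character(seqnames(gr)),
                    start = start(gr), end = end(gr),
                    id = rd$id, origin = rd$origin,
                    stringsAsFactors = FALSE)
    dh <- as.data.frame(H)
    names(dh) <- paste0("height_", colnames(H))
    dc <- as.data.frame(C)
    names(dc) <- paste0("count_", colnames(C))
    d <- cbind(d, dh, dc,
               data.frame(mean_a = rd$mean_a, mean_b = rd$mean_b,
                          sem_a = rd$sem_a, sem_b = rd$sem_b,
                          log2_ratio = rd$log2_ratio,
                          avg_height = rd$avg_height,
                          quartile = rd$quartile))
    d <- d[order(d$chrom, d$start, d$end), , drop = FALSE]
    writeTsv(d, file)
}

#' Human-readable run report
#'
#' Re-reads the manifest and stage outputs of a completed run and
#' writes `report.txt`, a plain-text digest of per-stage headline
#' numbers (peak counts, SSI removal rates, differential counts,
#' group sizes, enrichment rows). Nothing is recomputed; every number
#' is read back from a stage output.
#'
#' @param outdir pipeline output directory.
#' @return invisibly, the report path.
#' @export
writeReport <- function(outdir) {
    manifestPath <- file.path(outdir, "manifest.tsv")
    if (!file.exists(manifestPath)) stop("no manifest in ", outdir)
    man <- utils::read.table(manifestPath, sep = "\t", header = TRUE,
                             colClasses = "character")
    lines <- c("ssiCistrome pipeline report", strrep("=", 27), "")
    for (i in seq_len(nrow(man)))
        lines <- c(lines, sprintf("stage %-9s %s", man$stage[i],
                                  man$status[i]))
    lines <- c(lines, "")
    countLines <- function(f) length(readLines(file.path(outdir, f)))
    for (cond in CONDITIONS) {
        fullBed <- sprintf("peaks_%s_full.bed", cond)
        retBed <- sprintf("retained_%s.bed", cond)
        if (file.exists(file.path(outdir, fullBed))) {
            nFull <- countLines(fullBed)
            nRet <- countLines(retBed)
            lines <- c(lines, sprintf(
                "%s: %d full-pool peaks, %d retained by SSI (%.1f%% removed)",
                cond, nFull, nRet,
                if (nFull) 100 * (nFull - nRet) / nFull else 0))
        }
    }
    regPath <- file.path(outdir, "regions.tsv")
    if (file.exists(regPath)) {
        reg <- utils::read.table(regPath, sep = "\t", header = TRUE)
        lines <- c(lines, sprintf(
            "consolidated regions above height threshold: %d",
            nrow(reg)))
    }
    diffPath <- file.path(outdir, "differential.tsv")
    if (file.exists(diffPath)) {
        dd <- utils::read.table(diffPath, sep = "\t", header = TRUE)
        lines <- c(lines, sprintf(
            "differentially bound regions: %d of %d",
            sum(dd$significant %in% c(TRUE, "TRUE")), nrow(dd)))
    }
    grpPath <- file.path(outdir, "groups.tsv")
    if (file.exists(grpPath)) {
        gg <- utils::read.table(grpPath, sep = "\t", header = TRUE)
        tt <- table(gg$group)
        lines <- c(lines, paste("regulation groups:",
            paste(sprintf("%s=%d", names(tt), as.integer(tt)),
                  collapse = " ")))
    }
    enrPath <- file.path(outdir, "enrichment.tsv")
    if (file.exists(enrPath)) {
        en <- utils::read.table(enrPath, sep = "\t", header = TRUE)
        for (i in seq_len(nrow(en)))
            lines <- c(lines, sprintf(
                "genes bound (%s): %.1f%% (n=%d)", en$category[i],
                en$pct_bound[i], en$n_genes[i]))
    }
    out <- file.path(outdir, "report.txt")
    writeLines(lines, out)
    invisible(out)
}
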