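# Shared heavy fixtures, computed once per test run and memoized.

.studyCache <- new.env(parent = emptyenv())

# full default-scale pipeline run (the study conditions); reused by the
# acceptance tests that interrogate different aspects of the same run
acceptanceRun <- function(seed = 1L) {
    key <- sprintf("run_%d", seed)
    if (!is.null(.studyCache[[key]])) return(.studyCache[[key]])
    outdir <- file.path(tempdir(), sprintf("ssi_accept_%d", seed))
    cfg <- pipelineConfig(outdir = outdir, seed = seed)
    manifest <- suppressWarnings(suppressMessages(runPipeline(cfg)))
    genome <- readChromSizes(file.path(outdir, "sim", "chrom.sizes"))
    truth <- utils::read.table(file.path(outdir, "sim",
                                         "truth_sites.tsv"),
                               header = TRUE, sep = "\t")
    .studyCache[[key]] <- list(outdir = outdir, cfg = cfg,
                               manifest = manifest, genome = genome,
                               truth = truth)
    .studyCache[[key]]
}

# small, fast study for unit-level checks
smallStudy <- function(seed = 5L) {
    key <- sprintf("small_%d", seed)
    if (!is.null(.studyCache[[key]])) return(.studyCache[[key]])
    cfg <- simulationConfig(
        seed = seed, nChroms = 1L, chromBp = 400000L, nGenes = 20L,
        nTrueSites = 30L, nArtifactSites = 4L, nReplicates = 3L,
        depthPerReplicate = 30000L)
    .studyCache[[key]] <- suppressWarnings(simulateStudy(cfg))
    .studyCache[[key]]
}
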