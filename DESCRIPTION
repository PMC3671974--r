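Package: ssiCistrome
Title: Replicate-Consistent ChIP-seq Peak Calling and Quantitative
    Cistrome Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A toolkit for reproducibility-aware analysis of replicated
    transcription-factor ChIP-seq experiments across two physiological
    conditions. Implements the single sample independence (SSI) test, a
    leave-one-out filter that retains a peak called on the pooled
    replicates only if a similar peak is still called after excluding
    any individual replicate, together with the downstream quantitative
    cistrome pipeline: window-based peak calling on pooled tag
    libraries, consolidation of condition-level peak sets into
    high-confidence binding regions with per-replicate fragment-pileup
    heights in reads per million, exact-binomial differential-binding
    tests with Benjamini-Hochberg control, cAMP-response element (CRE)
    motif classification, position-weight-matrix TATA-box promoter
    scanning with TSS-distance-matched background sampling, genomic
    feature annotation relative to transcription start sites,
    integration with differential gene-expression tables into
    induced/repressed/no-change regulation groups, and co-localization
    profiles of secondary factors. A fully seeded synthetic-data
    generator with ground-truth tables supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    SummarizedExperiment,
    yaml
Suggests:
    testthat (>= 3.0.0)
biocViews: ChIPSeq, PeakDetection, DifferentialPeakCalling,
    MotifAnnotation, Epigenetics, QualityControl
Config/testthat/edition: 3
RoxygenNote: 7.3.3
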