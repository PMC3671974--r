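---
title: "Replicate-consistent peak calling and quantitative cistrome analysis with ssiCistrome"
author: "ssiCistrome authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Replicate-consistent peak calling and quantitative cistrome analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssiCistrome)
```

# The problem

Peak calling on replicated transcription-factor ChIP-seq is usually run
on a pooled read set, because pooling maximizes depth. The price is
that a sufficiently strong artifact in a *single* replicate — a PCR
stack, a copy-number blip, a mapping pile-up — can drive a peak call in
the pool, and nothing in the pooled analysis reveals that the evidence
comes from one library. Conversely, comparing *per-condition peak
lists* (the common Venn-diagram approach) systematically overstates
condition-specific binding, because peak callers have an appreciable
false-negative rate near their detection threshold and provide no
estimate of it: a site called in one condition and missed in the other
is usually bound in both.

`ssiCistrome` implements a two-part answer for a two-condition,
five-replicate liver ChIP-seq design (fasted vs re-fed):

1. **The single sample independence (SSI) test.** Peaks are called on
   the pool of all $n$ replicates and again on every pool of $n-1$
   replicates. A full-pool peak is retained only if a similar peak
   (by default, $\ge$ 1 bp overlap) is called in *every* leave-one-out
   pool. A peak whose evidence lives in one replicate disappears
   exactly when that replicate is excluded, so it is filtered, and the
   removal is attributed to the replicate whose exclusion killed it.

2. **Quantification instead of call-set comparison.** The retained
   per-condition peak sets are union-merged into consolidated regions,
   and the ChIP signal is quantified in *every* replicate of *both*
   conditions at every region — maximum fragment-pileup height in
   reads per million (RPM), and raw overlapping-fragment counts —
   regardless of which condition produced the call. Differential
   binding is then a statistical statement about counts, not about
   presence or absence in a peak list.

Downstream, the package classifies regions by CRE motif content,
annotates them against gene models, links them to target genes,
partitions them by the expression response of those genes, and profiles
co-localized secondary factors — the full integrative path from
cistrome to transcriptome.

# The pipeline, stage by stage

## Tag model and pooling

Reads enter as tagAlign/BED6 and are reduced to stranded 5′-end
positions. Redundant reads (identical chromosome, 5′ position and
strand) are removed **within each replicate** before any pooling;
pooling itself is a multiset union with no cross-replicate
deduplication, so `nTags` of a pool is the sum over members. In memory
all coordinates follow the `GRanges` convention (1-based, closed); the
0-based half-open BED convention applies on disk only and is shifted at
the I/O boundary. Using the container's native convention everywhere
internally was a deliberate choice: a single convention, enforced by
the container library, removes the whole class of off-by-one bugs that
mixed conventions invite.

## The built-in caller

The caller is a deliberately simple, fully specified stand-in for the
external callers practitioners use (and any external caller's BED
output can be substituted via `readPeakBed()` — the SSI filter only
consumes `PeakSet` objects). It slides 200 bp windows every 50 bp,
extends each tag to the average fragment length (108 bp) in its strand
direction, counts fragments overlapping each window, and computes a
Poisson upper-tail p-value against the larger of the global rate and a
local rate estimated over 10 kb around the window (window excluded).
Windows with fewer than 4 fragments are not tested. Window p-values
are Benjamini–Hochberg adjusted at a 5% FDR; overlapping significant
windows are merged into peaks; the summit is the leftmost position of
maximal coverage (leftmost on ties, for determinism), and the peak
height is the maximal coverage scaled to RPM. The caller has no hidden
randomness: identical inputs give identical output.

Two divergences from the external tools are intentional and
documented: window-level multiple testing uses Benjamini–Hochberg
rather than an empirical FDR, and peaks are variable-width merged
windows rather than fixed-width calls. Both choices favour exact
testability.

## The SSI filter

`ssiFilter()` takes the full-pool `PeakSet` and the $n$ leave-one-out
`PeakSet`s. "A similar peak" is not defined by the original procedure
text, so the weakest defensible rule — $\ge$ 1 bp interval overlap —
is the default, with a summit-distance rule (`match = "summit"`)
available; tightening the rule can only shrink the retained set.
Peaks within each set are already disjoint (the caller merges
overlapping windows; `readPeakBed` inputs should be, and merged sets
are, non-overlapping), which the match rule assumes. Two per-replicate
removal tallies are reported, because both are informative: the count
of peaks whose *only* failing pool excludes replicate $r$ (clean
attribution), and the count of removed peaks per failing pool (peaks
failing several pools counted once per pool).

## Consolidated regions and the height threshold

`mergeConditionPeaks()` union-merges the two SSI-filtered condition
sets, quantifies every region in every replicate, and keeps regions
whose average height — the unweighted mean of the two condition means,
the most direct reading of "average peak height across both
conditions" — exceeds 0.35 RPM. That threshold is the empirical
reproducibility cutoff established by ChIP-qPCR validation in the
source study; it is a configurable argument with 0.35 as the default.
The threshold is applied after merging (the procedure text orders it
that way). Retained regions are ranked into height quartiles; ties are
broken by coordinate order so quartile sizes stay within one of
$n/4$ even when heights tie exactly.

The log2 condition ratio uses a pseudocount of 0.01 RPM in numerator
and denominator so that zero-height regions stay finite; 0.01 RPM is
two orders of magnitude below the height threshold, so it never
dominates a retained region.

## Differential binding

The original analysis used a negative-binomial count framework
(EdgeR, "default parameters", 10% FDR). Reproducing that machinery
would make this package a wrapper around a black box with an
under-specified 2013 configuration; instead `differentialTest()` is an
exact conditional binomial test on pooled counts: conditional on the
total count $x_f + x_r$ of a region, $x_f$ is Binomial with success
probability $N_f/(N_f+N_r)$ under the null of proportional binding,
and the two-sided p-value sums outcome probabilities not exceeding
that of the observed outcome. Benjamini–Hochberg control at 10% FDR
follows. This test is exactly enumerable (hence exactly testable) but
**anti-conservative under biological overdispersion**: it conditions
away library-size variation but not replicate-to-replicate biological
variance. An optional method-of-moments dispersion-inflation factor
(`estimateDispersionInflation()`) scales counts down before testing as
a crude correction; the default is no inflation, and outputs should be
read with this caveat. The observed consequence on simulated data —
where per-site fold variation is real — is many more significant
regions than a dispersion-aware test would report; this is the
documented divergence, not a bug.

## Motif analysis

CRE classification follows the fixed rules: a 100 bp window centered
on the region midpoint (center −49 to center +50 of a 1-based center;
an octamer must be fully contained) is **FULL_CRE** if any 8-mer is
within Hamming distance 1 of `TGACGTCA` (25 of the 65,536 octamers
qualify), else **HALF_CRE** on an exact `TGACG` or `CGTCA` match,
else **NON_CRE**. `N` never matches. The procedure text names both
pentamers while the figure legend names only `TGACG`; both-strands is
the default and `strictForwardHalf = TRUE` reproduces the narrower
reading. Because the octamer is palindromic and the pentamer pair is
closed under reverse complement, classification is strand-symmetric.

PWM scanning is log-odds with a pseudocount of 0.5 per count cell and
a uniform background — values chosen for finiteness and convention,
since the original scanner's internal scale is not published. A gene
is TATA-containing when a hit with score $\ge$ 6 starts within 250 bp
of its TSS (inclusive; a hit at 251 bp does not count). The score-6
threshold is kept for interface fidelity, but note it is a threshold
on *our* log-odds scale; with the shipped TATA matrix it reproduces
the expected behaviour (planted TATA boxes recovered, a background
rate of a few percent). The shipped matrix
(`inst/extdata/tata_synthetic.jaspar`) is a **synthetic,
consensus-derived** count matrix in JASPAR text format — ten
near-deterministic core positions spelling `GTATAAAAGG` plus three
weakly G-biased flanks — not a copy of any database entry; it is
labelled synthetic for exactly that reason.

Background sampling for motif enrichment matches the signed
nearest-TSS distance distribution of the foreground, using per-side
bins at 200 bp / 2 kb / 10 kb / 50 kb. These particular breakpoints
mirror every other TSS-relative window in the pipeline (promoter
−2 kb…+200 bp, distal −10 kb, intergenic-proximal 50 kb), which is
the most defensible reading of "maintain the general distribution of
distances"; CpG matching is out of scope along with de novo motif
discovery. Sampling is rejection-based from a uniform candidate pool,
excludes the foreground intervals, is deterministic under the seed,
and falls back to the nearest non-empty bin with a warning when a bin
has no candidates.

## Annotation and integration

`classifySite()` compares the exact region center to the gene models.
The source text lists the feature classes in one sentence without an
explicit precedence, so the default order is
PROMOTER (−2 kb…+200 bp of any TSS, strand-relative) > FIVE_UTR
(5′UTR bases beyond +200 bp) > EXON_CDS > THREE_UTR > INTRON >
INTERGENIC — exonic evidence beats intronic evidence from another
transcript, which is the biologically sensible resolution — and
`mode = "literal"` ranks introns first, reproducing the literal
sentence order. First-intron membership and within-50 kb-of-TSS (for
intergenic sites) are flagged. A second, independent classifier
(`classifySiteRegulatory()`) implements the proximal/distal/intronic/
exonic scheme rather than overloading the first. Nearest-TSS ties
break toward the gene earlier in coordinate order, for determinism.

Target mapping links a site to every gene whose strand-relative
window [TSS − 10 kb, TES] contains the site center; boundaries are
inclusive, so 10,000 bp upstream links and 10,001 bp does not.
Regulation groups then partition sites by the expression response of
linked genes with precedence INDUCED > REPRESSED > NO_CHANGE >
UNASSIGNED; the source never states how a site linked to both an
induced and a repressed gene is handled, so the precedence is applied
and every such conflict is counted and reported. UNASSIGNED exists
precisely for sites whose only links are to unmeasured genes (or that
have no links); linked symbols absent from the expression table are
treated as unmeasured and logged.

Enrichment statistics are two-sided Fisher exact tests; the odds ratio
is reported as the sample ratio $ad/bc$ (infinite or undefined at zero
margins, reported as such). Secondary-factor co-localization uses the
same RPM fragment-pileup height at the primary factor's regions, and
`averageProfile()` bins RPM coverage around group anchors; bins
truncated by a chromosome edge are excluded from the group mean for
the affected anchors only.

# The synthetic-data generator

The generator exists so that every pipeline property can be tested
against known truth. Its defaults *are* the study conditions: two
1 Mb chromosomes, 5 + 5 replicates of 100,000 tags, 200 constitutively
bound true sites at 5× background enrichment, 20 artifact sites whose
tags are drawn only in one owning replicate of one condition at 15×
enrichment, a log-normal per-site fasted/re-fed fold with median 1.3
(σ = 0.25 in log2, applied symmetrically as $\sqrt{f}$ up and
$1/\sqrt{f}$ down so total depth is preserved), a CRE motif mix of
0.5/0.3/0.2 full/half/none at true sites, 20% TATA-containing
promoters (the consensus planted 25–35 bp upstream of the TSS), an
expression table flagging 15% of measured genes as differential at
|fold| ≥ 1.5, and bound-gene rates of 60% among DE genes vs 33% among
the rest.

Design choices that make the truth *recoverable*, not merely planted:

* **Tag placement.** Fragment 5′ ends are uniform on
  [center − 108, center) for + tags and mirrored for − tags, so
  fragment coverage peaks exactly at the site center — simple and
  analytically checkable; no attempt is made to model real fragment
  size distributions.
* **Site spacing.** Planted sites keep ≥ 1 kb mutual distance (well
  above the 2 × fragment floor the construction requires), so two
  sites never merge into one called peak and per-site bookkeeping
  stays exact.
* **Sparse gene geometry.** 120 compact genes (2–8 exons of
  80–150 bp) separated by ≥ 12.2 kb, so the 10 kb target windows of
  adjacent genes can never both contain a site planted within
  [TSS − 2 kb, TES] of its gene; true sites not assigned to a gene
  are placed outside *every* target window. Without this sparsity the
  10 kb windows tile a 2 Mb genome and every gene trivially counts as
  bound, destroying the planted 60%/33% contrast. With 120 genes that
  contrast is recovered in rate but a Fisher test of it has limited
  power; the enrichment significance claim is therefore evaluated at
  a 500-gene study size (on a proportionally larger genome), the size
  at which the claim is meaningful.
* **Motif scrubbing.** After planting, accidental CRE matches within
  ±60 bp of every true site center are mutated away (the planted
  motif itself is protected), so the planted motif class *is* the
  class the classifier measures.
* **Artifacts.** Artifact tags are drawn only in the owning replicate
  and nowhere else — the cleanest construction exercising the SSI
  contract: the artifact is callable whenever its replicate is in the
  pool and undetectable otherwise.
* **Conservation and determinism.** Every emitted library holds
  exactly the configured tag count before deduplication, and every
  artifact of a run is a pure function of the configuration and seed
  (the layout, sequence, tag and secondary-factor streams each derive
  a fixed offset from the master seed, so the individually exported
  generators are mutually consistent with the one-shot
  `simulateStudy()`).

What the generator deliberately does **not** emulate: real base
composition or CpG structure, mappability, copy-number variation,
fragment-length dispersion, input-chromatin structure, or
overdispersion beyond the per-site log-normal fold. Passing tests on
this generator therefore demonstrate the *logic* of the pipeline —
filtering, quantification, attribution, integration — under its own
assumptions; they do not demonstrate robustness to the artifacts of
real sequencing data.

# Validation sizes and numerical choices

The test suite validates each operation against an independent
brute-force oracle (per-base pileup arrays, all-pairs overlap loops,
hypergeometric enumeration, a from-definition step-up BH, exhaustive
octamer enumeration) and runs the full pipeline end-to-end on the
default simulation, checking byte-identical reruns, ≥ 95% retention of
true sites, complete removal and correct attribution of artifacts, and
recovery of the planted qualitative structure. The global-fold
recovery check runs at a lower background density (two 4 Mb
chromosomes, 400 sites, same depth), where deduplication losses and
background admixture — both of which compress measured height ratios
toward 1 at high tag density — are small enough that the planted
median 1.3-fold is recovered within ±0.1 in log2. The differential
null calibration uses 2,000 regions at a pooled Poisson mean of 100
per condition, a typical regional depth at these library sizes. These
problem sizes are the package's validation choices and are restated in
the test files.

Remaining numerical conventions in one place: summit ties leftmost;
quartile ties by coordinate order; BH via `stats::p.adjust`;
Fisher p-values via `stats::fisher.test` (cross-checked against
enumeration); binomial p-values via `stats::binom.test` (its
two-sided rule is the definition used); PWM pseudocount 0.5, uniform
background, N scores −∞; log2 ratio pseudocount 0.01 RPM; TSV floats
at 6 significant digits with rows ordered by (chrom, start, end);
pipeline configuration files are YAML (a single nested text format
covering the same need as any other config syntax).

# Known limitations

* The binomial differential test is anti-conservative under real
  biological overdispersion (see above); the inflation factor is a
  heuristic, not a dispersion model.
* The caller's local background is a simple rate estimate; there is
  no input-chromatin subtraction beyond it, no paired-end support,
  and no attempt to reproduce any external caller's scoring.
* The TATA score threshold is interface-compatible (score ≥ 6) but
  lives on this package's log-odds scale; absolute rates depend on
  the matrix used.
* Per-condition peak-overlap percentages are reported with both
  denominators (union-merged regions, and per-set fractions) because
  the single-number form is ambiguous; consumers should pick one and
  say which.
* The generator's idealizations listed above bound what a green test
  suite can claim about field data.
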