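---
title: "Cross-platform expression integration: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-platform expression integration: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossExpress)
```

# The integration model

crossExpress treats every expression measurement unit — a microarray
probe, a sequencing read, a SAGE/MPSS tag — as a *tag*: a stranded
genomic interval with an identifier. Expression units are *targets*:
user-supplied interval collections named `superID@subID`, where the
superID is the unit expression is reported for (typically a gene) and
the subID a sub-feature (typically an exon). The pipeline is a fixed
chain:

1. **MATCH** — overlap-join tag alignments against target intervals,
   and against each interval-based exclusion feature;
2. **ANNOTATE** — per distinct tag, record matched full ids, matched
   superIDs, and one hit flag per feature; derive the `multiTarget`
   feature (tags hitting ≥ 2 distinct superIDs);
3. **EXCLUDE** — drop tags flagged by any user-selected feature, plus
   tags matching no target;
4. **SUMMARIZE** — per platform, reduce surviving tags to one value per
   superID (median polish for closed platforms, RPKM for open ones);
5. **JOIN** — combine per-platform summaries into one superID-by-sample
   matrix (intersection by default, union optional).

The assumptions worth stating: tag-to-target assignment is purely
positional (no sequence re-alignment); a tag with several genomic
alignments is one measurement whose trustworthiness depends on *all*
its alignments; exon-spanning (spliced) alignments are not modelled —
each alignment is a single contiguous interval; and platforms are
independent until JOIN, so no cross-platform normalization is applied
(the closed columns stay on log2 scale, the open columns stay RPKM).

## Coordinates and dialects

Internally a single convention is used everywhere (ranges are held in
`GRanges`, i.e. 1-based closed; file readers and writers convert). BED
input is 0-based, and the `dialect` flag settles the one genuinely
ambiguous convention in the wild: `standard` reads the end column as
exclusive (UCSC), `closed_end` as inclusive, which is what you get
from the common post-processing recipe `end = start + length(tag) - 1`
applied to aligner output. Rather than guessing a file's convention,
the flag makes the choice explicit at the boundary; nothing else in
the package knows dialects exist. Under half-open semantics touching
intervals share no base, so the sweep orders end events before start
events at equal positions — the only tie rule consistent with that
reading.

## The sweep-line matcher

The matcher sorts the 2(nq + ns) interval endpoints once and walks
them in order, holding the currently open intervals of each side in an
active store with O(1) insert and swap-remove. When an interval opens,
it pairs against the opposite active set; since both are open at the
sweep position they overlap by at least one base, and the actual
overlap length is checked against `minOverlap` at emission. Cost is
O(n log n) sorting plus O(n + k) for k inspected overlapping pairs.
Two policies are exposed:

- `strandPolicy` (default `require`): intervals pair only when strands
  are equal or either is unspecified. Targets and aligner output are
  stranded, so requiring agreement is the safe default; feature
  matching (SNPs) always ignores strand because such annotations apply
  to both strands.
- `minOverlap` (default 1 base): the field has no universal minimum-
  overlap convention for tag-to-target matching, so one shared base
  counts and the threshold is a parameter.

Duplicate (tag, target) id pairs — one tag overlapping several exons
of a target, or via several alignments — collapse to one pair. The
package also ships `matchAllPairsOracle`, the definitionally correct
O(n²) nested comparison, used throughout the tests as an independent
check; the two paths share only output formatting, not overlap logic.

## multiTarget granularity

`multiTarget` is defined at the superID level: a tag hitting two exons
or isoforms of *one* gene is measuring that gene, not
cross-hybridizing. A `level = "full"` switch flags at full-id
granularity for users whose subIDs are isoforms they want separated.
Because cross-hybridization is a property of the tag, all alignments
of a tag contribute to its matched set before the ≥ 2 test.

## Summarization

**Closed platforms.** For each superID the surviving probes' rows are
transformed `log2(x + logOffset)` (`logOffset` default 1 so
nonnegative intensities are safe; with `logOffset = 0` a nonpositive
cell is an error naming the probe) and decomposed by Tukey median
polish: alternating row- and column-median sweeps, medians of the
effect vectors folded into the overall term, stopping when the sum of
absolute residuals improves by ≤ `tol` (default 0.01, relative) or
after `maxIter` (default 10) sweeps — the conventional settings for
RMA-style summarization. The reported value is
`overall + columnEffect`, per sample. Median polish is robust to a
minority of aberrant probes, which is exactly why probe-level
filtering still matters only when contamination is not a small
minority of a probe set. Even-count medians use the midpoint of the
middle two values. The decomposition
`x = overall + row + col + residual` holds exactly at every iteration,
and the implementation is checked against `stats::medpolish` on random
matrices.

**Open platforms.** RPKM per superID: `10⁹ · C / (N · L)`. `C` counts
*distinct* surviving reads (a read matching a superID via several
exons or alignments counts once; `perAlignment = TRUE` switches to
per-alignment counting). `L` is the width of the union of the
superID's sub-intervals with overlaps merged, so duplicated exon
annotation never double-counts length. `N` is the number of distinct
reads aligned in the platform's input, counted *before* exclusion
filtering (the reads were mapped, whether or not we trust them for
quantification); `rpkmPostExclusion = TRUE` switches to the filtered
count. One open platform corresponds to one sample and contributes one
column. The conservation identity Σ RPKM·L·N/10⁹ = Σ C is asserted in
the tests.

## Sample tables and quantile normalization

`bindSamples` makes two passes so peak memory is one file plus the
running intersection: pass one reads only the id columns and
intersects them (keeping the first file's order), pass two fills one
column per file. Probe ids are free-form; `x:y` coordinate ids from
array text exports work unchanged. `quantileNormalize` implements the
definition directly — sort each column, average the sorted rows, map
the means back by each column's ranks — with ties receiving the
average of their tied positions' means (the standard tie rule; no tie
policy is canonical, so the simplest deterministic one is used). The
rank-assignment pass works one column at a time in `chunkRows` blocks.
With tie-free data every column's sorted values equal the common mean
vector exactly, making the transform idempotent; with ties the
averaged values can differ slightly between columns, which is the
price of the tie rule and is documented rather than hidden.
Normalization is applied to values as given (raw or log) — the
transformation choice belongs to the summarization stage.

## Coverage tracks

`coverageBedGraph` computes base-resolution coverage over a window and
run-length-encodes maximal constant steps, dropping zero runs. Open
platforms: read count per base. Closed platforms: mean over covering
probes of each probe's mean intensity across samples, averaged on the
raw scale by default (`intensityScale = "log2"` switches) — averaging
before log is the choice that keeps a probe's track height equal to
its table value when only one probe covers a base. One track per
platform; `forward`/`backward` strand keywords restrict to a strand,
with unspecified-strand tags always counted.

## Evaluation utilities

*Gene coverage* is the fraction of reference superIDs present in a
summary. *CAT curves* report |top-n(A) ∩ top-n(B)| / n over a grid of
list sizes (default 50–2000 by 50, truncated to the rankings, and
configurable — small synthetic studies need proportionally smaller
grids). *Fold-change ranking* orders genes by |mean(A) − mean(B)| on
log2 values, adding a pseudocount of 1 before log2 for linear-scale
RPKM columns; ties break lexicographically so every ranking is
deterministic. *q-value ranking* uses a pooled-variance two-sample t
statistic on log2 values with Benjamini–Hochberg adjustment — BH is
the deterministic, parameter-free FDR choice; zero-variance genes get
a small variance floor (default 1e-8) rather than an undefined
statistic. *Correlation matrices* are Spearman (Pearson on ranks),
with constant columns reported as NA with a warning.

# The synthetic data generator

`generateFixture` builds a complete study from a `FixtureSpec`; with a
fixed seed every file is byte-reproducible. What it emulates:

- a toy genome of non-overlapping multi-exon genes (300-bp exons,
  200-bp introns, 1-kb gaps, genes alternating strand over
  `chromCount` chromosomes);
- a closed platform whose probes tile each gene's 3'-most exon —
  3'-biased probe design — with log-normal intensities around per-gene
  log2 means (noise `closedNoiseSd`, default 0.25);
- open platforms, one per sample, whose 25-bp reads spread uniformly
  across all exons with negative-binomial per-gene counts
  (`readDispersion`, default 0.2; 0 gives Poisson);
- a group contrast: `nDeGenes` spiked genes at ± `deLog2Effect`
  (default 10 genes at 2), on top of a continuous per-gene tissue
  effect (`tissueEffectSd`, default 1) truncated at half the spike so
  the planted genes remain the extreme tail by construction — tissue
  contrasts show widespread differential expression, not a handful of
  changes on a null background;
- a per-gene closed-platform tag effect (`platformEffectSd`, default 1
  log2 unit) shared by a gene's probes and constant across samples:
  hybridization efficiency differs per probe set, which leaves
  within-platform replicate agreement intact while decoupling the two
  technologies — the reason cross-platform correlations come out
  moderate while within-platform correlations are very high. The
  effect must be per gene, not per probe: a per-probe offset would be
  absorbed exactly by median polish's row effects;
- planted contamination: `fractionMultitargetTags` of tags carry a
  second alignment in a partner gene — a cross-hybridizing probe's
  intensity measures the *sum* of both genes' signal, a
  cross-hybridizing read inflates the partner's count; SNPs are fixed
  1-bp positions whose per-exon density is calibrated so the expected
  fraction of tags overlapping one equals `fractionSnpTags`, and a
  SNP-overlapping probe hybridizes unpredictably (its level is drawn
  independently of its gene).

Ground truth is written alongside: the DE gene list, the planted
multiTarget tags (exact, because genes never overlap), and the
SNP-overlapping tags computed with `GenomicRanges::findOverlaps` — an
overlap oracle independent of the package's own matcher, so
recovering the truth through the pipeline is a genuine two-route
check.

What the generator does *not* emulate: sequencing error and quality,
exon-spanning reads, overlapping gene models, GC and length biases,
batch effects, isoform switching. Tests passing on these fixtures
demonstrate that the pipeline's accounting — matching, filtering,
summarizing, joining — is correct and that planted signal of realistic
size survives it; they do not certify performance on real data with
the artefacts above.

# Problem sizes and test design

The test-suite and the acceptance script run at desk scale, chosen to
finish in minutes while leaving the measured properties meaningful:
matcher correctness on 200 randomized instances of up to 10³ intervals
per side against the brute-force oracle; scaling measured at 10⁴, 10⁵
and 10⁶ intervals with fixed overlap density (the log-log slope stays
near 1, far from quadratic); quantile normalization on 10⁴ × 20
matrices; median polish against the reference implementation on 100
random matrices up to 20 × 10; end-to-end exclusion recovery on the
default 100-gene study; CAT-curve comparisons on 500-gene studies
(top-list overlap at small list sizes is coarse — proportions move in
steps of 1/n — so the deeper fixture keeps the dominance measurement
stable); correlation structure across 10 seeds of the default study.

# Known limitations

- Gapped/spliced alignments are out of scope; reads spanning exon
  junctions must be handled upstream or are lost to matching.
- No cross-platform normalization: the combined table deliberately
  mixes log2 intensities and RPKM columns, and rank-based downstream
  methods (Spearman, CAT) are the intended consumers.
- Binary array formats are not parsed; the package consumes text
  exports (probe-id/value tables).
- `bindSamples` assumes each per-sample file fits in memory one at a
  time; `quantileNormalize` holds the matrix in memory and bounds only
  the extra working set of the rank-assignment pass.
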