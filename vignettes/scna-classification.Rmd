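---
title: "Classifying somatic copy number alterations: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying somatic copy number alterations: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scnatlas)
```

## The model

`scnatlas` operates on segmented copy-number data: per-sample tables of
genomic intervals with a segment mean, interpreted directly as the log2
tumor/normal copy ratio with no re-centering or ploidy correction. Two
thresholds call direction, three rules assign a mutually exclusive class:

| decision | rule | default | convention |
|---|---|---|---|
| amplified | log2 ratio above threshold | 0.32 | strict (>) |
| deleted | log2 ratio below threshold | −0.42 | strict (<) |
| indel | event length under bound | 10 kb | strict (<) |
| aneuploidy | max eligible arm fraction over bound | 75% | strict (>) |
| gene call | covered gene fraction at/over bound | 50% | inclusive (≥) |

The asymmetric direction thresholds reflect the usual asymmetry of log
ratios for single-copy gain (log2 3/2 ≈ 0.58) versus single-copy loss
(log2 1/2 = −1) diluted by normal-cell admixture and intra-tumor
heterogeneity; both are plain parameters of `scna_params()`, as are all
other bounds, so either strictness convention can be reproduced by nudging a
threshold by one serialization unit.

Reading "above", "below", "more than" and "smaller than" as strict
inequalities, and "at least" as inclusive, follows the plain meaning of
those words; the boundary behaviour is pinned by tests at each constant
(a 10,000-bp event is *not* an indel; a segment at exactly 75% of an arm is
*not* an aneuploidy; a gene covered at exactly 50% *is* called).

### Arm geometry and aneuploidy

A `genome_build` carries chromosome lengths and p/q arm intervals
(zero-based half-open internally; conversions happen only at file
boundaries). The aneuploidy test evaluates the covered fraction of **each**
arm of the event's chromosome and takes the maximum over eligible arms, so a
centromere-spanning or whole-chromosome event is a single aneuploidy, never
one per arm. This per-arm-maximum treatment of centromere-spanning events is
a declared design decision: evaluating the fraction on a combined p+q span
would conflate two arms' geometry, and counting per arm would double-count
single biological events.

Short arms of acrocentric chromosomes (human chr13/14/15/21/22; arbitrary
arms in toy genomes) carry essentially no unique sequence, so they are
excluded from the aneuploidy test only — their base pairs still count toward
event length and percent-genome denominators. Chromosome Y is excluded from
the default analysis set (denominators and per-chromosome tables); X is
included. A centromeric gap between the arm extents is permitted, and the
indel rule uses segment length, not arm-assigned length.

### Ambiguities resolved as modes

Two points the source conventions leave genuinely open are implemented as
explicit modes rather than silent choices:

- **Per-chromosome SCNA distribution.** The normalization of per-chromosome
  SCNA proportions by chromosome length is stated once as a division
  ("normalized by chromosome length") and once, in a figure formula, as a
  multiplication. `chrom_distribution(mode = "divide")` (default) reports
  the per-Mb density `(n_c/N)/L_c`; `mode = "literal"` reports
  `(n_c/N)·L_c`.
- **Gene overlap.** "Overlap with a SCNA" can mean a single segment or the
  union of segments; segmentation granularity can split one biological event
  into several rows, so the union is the default and `union = FALSE` gives
  the single-segment reading. Only SCNA-class events count toward gene
  calls by default (`include_classes`), matching the scoping of the gene
  analysis to SCNAs; indels and aneuploidies can be opted in.

Adjacent same-direction segments are *not* merged before classification by
default (merging changes event counts); `classify_cohort(merge_gap = ...)`
enables gap-tolerant merging with length-weighted mean ratios.

## Statistics

Per-type amplification-vs-deletion comparisons use the unpaired two-sided
Wilcoxon rank-sum test (`stats::wilcox.test`), with the exact enumeration
when both groups have ≤ 25 observations and no ties, and the
tie/continuity-corrected normal approximation otherwise. The star convention
is * p < 0.05, ** p < 0.01, *** p < 0.001, **** p < 0.0001, with boundary
values taking the weaker label. No multiple-testing correction is applied by
default (mirroring the per-type star displays this reproduces);
Benjamini–Hochberg is available via `compare_groups(adjust = "BH")`.

Spearman correlations (mid-rank product-moment, t-approximation p-values)
between per-sample amplification and deletion counts are reported at two
distinctly labeled scopes — across samples within each type, and across
types on the type means — because the two readings answer different
questions and either may be wanted.

Mean SCNA length is computed over SCNA-class events only (indels and
aneuploidies excluded). Per-sample summaries average within a sample first
(`cohort_tables`); the `scna_len_event` metric is instead a flat
recomputation over all events, which is what a pooled "mean ± s.d. SCNA
length" headline refers to. For per-chromosome length summaries, the
"normalized" variant divides the mean length by chromosome length in Mb —
the count-based normalization is the one specified upstream; this choice
for lengths is the package's own and is labeled in the output column name
(`mean_per_mb`).

## The synthetic cohort generator

`generate_cohort()` emulates the *decision structure* of tumor segment data,
not any particular cancer type's marginal distributions. Per sample:

- Event counts are negative-binomial per direction, with per-type means
  (defaults 4–18 amplifications, 3–13 deletions across five toy types,
  dispersion 4) spanning the order-of-magnitude burden differences seen
  between high-burden (OV/SARC-like) and low-burden (THCA/KIRC-like)
  cohorts. An optional shared gamma intensity (`coupling`) makes
  amplification and deletion counts positively correlated within a sample,
  emulating the observed within-sample coupling of the two directions.
- Classes are multinomial (default 30% indel / 60% SCNA / 10% aneuploidy,
  SCNA-dominant as in real pan-cancer tallies). SCNA lengths are log-normal
  (default meanlog log(1.2 Mb), sdlog 1.4, i.e. mean ≈ 3 Mb with a heavy
  right tail) truncated to the legal SCNA range of the target arm; indels
  are uniform in [300, 9500] bp; aneuploidies cover a uniform fraction in
  (75%, 100%] of an eligible arm.
- Every ratio keeps a guard margin (default 0.02 log2 units) from the
  calling thresholds and every length a margin (default 100 bp) from the
  size and arm-fraction boundaries, so classification of generated data is
  never ambiguous at serialization precision.

Placement is deterministic-feasibility based: free gaps within the chosen
arm are computed exactly and a start position is drawn uniformly from the
remaining slack, so an infeasible planted configuration is a hard error
before any file is written, never a silent truncation. Two structural
constraints make the truth tables exact by construction rather than by
re-running the pipeline:

- background SCNAs and indels never overlap census-gene territory, so the
  gene-call truth is exactly the planted incidence (aneuploidies may overlap
  genes; they are excluded from gene calling by default);
- within a sample all segments are pairwise disjoint, so percent genome
  altered is a plain sum of event lengths, independent of the package's
  union arithmetic — which is checked against it.

Because at most one arm-level event fits per arm, a sample whose drawn
aneuploidy demand exceeds the free-arm supply realizes the excess as large
sub-arm SCNAs; the truth table records realized classes, so truth
consistency is unaffected. Pair truth is derived combinatorially from the
generator's own gene-incidence table. Planted gene frequencies are realized
as exact rounded counts per type; a gene planted both singly and through a
pair accumulates the union of both incidences.

What passing tests on this generator do **not** show: robustness to
segmentation noise, probe-level artifacts, GC waves, purity/ploidy shifts,
or real per-cancer-type burden profiles — none of which are simulated.
Results on real SEG files inherit whatever upstream segmentation and
normalization produced them.

## Numerical and determinism choices

- Coordinates are zero-based half-open everywhere internally (length =
  end − start); SEG files are 1-based inclusive on disk, BED and cytoBand
  zero-based half-open, explicit arm tables 1-based inclusive. The
  pipeline's own intermediate TSVs keep internal coordinates.
- Interval unions and gene-coverage intersections go through
  IRanges/GenomicRanges (`reduce`/`intersect`/`findOverlaps`); tests compare
  them against brute-force base-pair marking oracles on toy genomes.
- All result tables are written with sorted keys and 6-significant-digit
  floats, making outputs byte-identical across re-runs and independent of
  in-memory row order. Ties in gene and pair rankings break
  lexicographically (by symbol, then pair), so top-k lists are reproducible.
- All generator randomness flows from a single integer seed; the same spec,
  build and seed reproduce files byte-for-byte.
- Degenerate inputs are reported as missing, not zero: mean SCNA length with
  no SCNAs, class mix of an event-free type, chromosome distributions with
  zero SCNAs, Spearman rho of a constant vector.

## Problem sizes used in the shipped checks

The test suite exercises: boundary grids of ~500–1000 points per decision;
oracle equivalence on 1,200 random events over a ≤ 10-Mb three-chromosome
toy genome; exact truth recovery on a 250-sample (5 types × 50) synthetic
cohort with planted genes and pairs; Wilcoxon type-I calibration over 2,000
null replicates at n = 20 per group; and double end-to-end pipeline runs for
byte-identity. These sizes give every check either exactness or comfortable
statistical power while keeping the whole suite in the low minutes on one
CPU.

## Known limitations

- No re-segmentation, GC correction, purity/ploidy inference, or
  allele-specific copy number: the segment means are taken as delivered.
- No significance model for co-occurrence (no permutation null): pair
  frequencies are raw fractions of tumors, as in the display this
  reproduces.
- p/q is the only sub-chromosome resolution; no cytoband-level geometry
  beyond deriving arm extents, and no assembly liftover — the genome build
  is an explicit input.
- The Wilcoxon exact path is capped at n ≤ 25 per group; beyond that the
  corrected normal approximation is used even where exact computation would
  be feasible.
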