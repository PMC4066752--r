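---
title: "Methods: chromatin states, exact motif thresholds and expression linkage"
author: "peakstates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chromatin states, exact motif thresholds and expression linkage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peakstates)
```

This vignette is the package's own account of the models and procedures it
implements, the parameters that matter, the design choices that were
genuinely open, and what the synthetic-data tests do and do not establish
about real data.

## 1. Coordinates and containers

All on-disk formats (BED, narrowPeak, chrom.sizes) are 0-based half-open;
in memory everything is a `GRanges` (1-based closed), and conversion
happens only in the readers/writers. Two intervals overlap iff they share
at least one base, so half-open abutting intervals do not overlap. Peak
summits are absolute positions (`summit` metadata column); a narrowPeak
summit offset of −1 is imputed as the interval midpoint and flagged
`summit_imputed`, so downstream stages can reject imputed summits if they
wish.

A summit extended by a flank *f* produces a window of width 2*f* + 1 with
the summit base included and centered (`include_summit = TRUE`, the
default). Peak callers and published pipelines are ambiguous about whether
a "±125 bp, 250 bp window" includes the summit base; both behaviors are
supported, and the default keeps the window symmetric about the summit.
The core-promoter window of a TSS at 0-based position *t* is
[*t* − 200, *t*) on the plus strand and [*t* + 1, *t* + 1 + 200) on the
minus strand: the TSS base itself is excluded symmetrically on both
strands.

## 2. Chromatin-state classification

Six mutually exclusive states are assigned from four histone-mark peak
sets (H3K4me3, H3K4me1, H3K27ac, H3K27me3) and core-promoter windows.
H3K4me3 with H3K27ac marks active promoters; H3K4me3 with H3K27me3 is
bivalent chromatin, i.e. poised promoters; H3K4me1 with H3K27ac marks
active enhancers; H3K4me1 without H3K27ac poised enhancers; H3K27me3 alone
closed chromatin; everything else is `other`.

Three details are interpretive choices rather than forced by the
definitions, and are therefore explicit and configurable:

* **Precedence.** A locus can satisfy several definitions (e.g. a bivalent
  promoter that also carries H3K4me1). The default order — promoters
  before enhancers, active before poised, closed last — follows the order
  in which the definitions are conventionally listed. The alternative
  order (active enhancer before poised promoter) is available, and
  `precedence_comparison()` reports every locus whose label changes, so
  rule-order sensitivity is visible rather than silent.
* **"Distal" quantified.** Enhancer states require distance from core
  promoters; no standard number exists. The default margin is 2000 bp,
  implemented as "no overlap with any core-promoter window extended by the
  margin", i.e. distance ≥ margin.
* **Poised enhancers lack H3K4me3.** Without this extra condition every
  bivalent promoter carrying incidental H3K4me1 would be re-labelled an
  enhancer under the alternative precedence. This is documented as an
  interpretation, not part of the published definitions.

Whether poised promoters must additionally lack H3K27ac is not specified
anywhere; the classifier does not require it (the active-promoter rule,
evaluated first, already captures H3K27ac-positive promoters).

TF peak groups are classified by their full interval by default; a
summit-position mode is available (`assign_peaks(mode = "summit")`),
since it is not knowable which convention a given published analysis used.
Joint regions of two factors are the merged intersections of overlapping
peak pairs — the strictest reading of "regions containing both" — with the
first contributing summit of the first group as representative summit
(midpoint, flagged, when none falls inside).

## 3. Exact PWM score distribution and the bit-score threshold

A position frequency matrix is turned into a log2-odds PWM with

entry(b, j) = log2(((count(b, j) + p·bg(b)) / (colsum(j) + p)) / bg(b)),

with total pseudocount p = 0.8 distributed by the background (common
JASPAR practice; configurable, p = 0 gives −Inf for zero counts). The
background model is the 0-order base composition of the supplied genome
(uniform for the synthetic default); no higher-order background is
implemented.

The null score distribution of a background word is computed exactly by
dynamic programming: per-column entries are rounded to an ε-bit grid
(default ε = 0.01; the acceptance tests use 0.001) and the four-outcome
per-column distributions are convolved column by column. −Inf entries send
their mass to a dedicated "impossible" bin outside the grid. The tail
function is **P(S ≥ t, S finite)** and is deliberately *not* renormalized
when impossible mass exists: it is then directly the per-position
false-positive probability of the cutoff t.

The threshold at rate α (default 10⁻⁴) is the smallest *support* score
with tail ≤ α. Restricting the search to the support matters: scores above
the maximum attainable score have tail 0 but can never be met by a real
hit, so when even the top support point carries more than α of mass the
threshold is *unattainable* and is reported as `Inf` with an
`unattainable` attribute — scanning then yields zero hits by construction.
For a width-W matrix under a uniform background the best word alone
carries 4⁻ᵂ probability, so α = 10⁻⁴ needs W ≥ 7; this is why the bare
6-bp E-box core cannot reach it and the shipped synthetic E-box is 8 bp
wide. The α here is a per-window-position type-I error rate of the null
score distribution — the quantity a score cutoff actually controls — not a
Benjamini–Hochberg style FDR over a hit list.

Scanning slides the PWM over the window and its reverse complement;
offsets are reported in forward-window coordinates, ties broken by smaller
offset then `+` strand (visible for palindromic E-box hits, which score
identically on both strands). Enrichment enters a 2×2 table as
presence/absence per window ("at least one site"), not hit counts, against
the same number of length-matched random genomic regions sampled uniformly
outside the peak set. Matching is by count and length only; GC matching is
not implemented. Both a one-sided Fisher exact test (via the
hypergeometric tail) and a one-sided pooled two-proportion z test are
reported, because published figure legends and methods sections name
either; neither is privileged. All alternatives are one-sided ("proportion
higher than background").

## 4. Expression linkage

Reads are counted into summit ±1000 bp windows (the flank is a parameter:
method descriptions and figure legends in the literature disagree between
±1000 and ±500; the package defaults to 1000 and exposes it), a read
counting for every window it overlaps by ≥ 1 base. An alternative
5′-end-containment mode is not implemented; overlap counting is the
default and only mode. Counts are normalized to reads per kbp
(count·1000/width), and log10(rpk + 0.1) keeps zero-count windows finite
(offset configurable). Windows are restricted to promoter-proximal peaks —
those overlapping a core-promoter window — before group comparison. The
primary test is the one-sided Wilcoxon rank-sum on rpk (rank-based, hence
offset-free); Welch's t on the log values is secondary; the rank-biserial
correlation and the group mean ratio are the effect sizes. Whether to
count reads in the extended window or the original peak interval is
ambiguous in published descriptions; the extended window is the default
(`expression_flank`), and passing `expression_flank` small with wide peaks
approximates the other reading.

## 5. The synthetic-data generator

`generate_dataset()` emulates the structure of a real ENCODE-style input
bundle at desk scale. Defaults (the package's reference study conditions,
chosen once):

* genome: 2 chromosomes × 1 Mb, i.i.d. uniform base composition;
* 500 regulatory regions of 600 bp, centers 4 kb apart (so enhancers are
  always ≥ 2 kb from promoters and no mark peaks from adjacent regions
  touch), with state proportions (.24, .16, .10, .12, .14, .24) over
  (active promoter, active enhancer, poised promoter, poised enhancer,
  closed, other), allocated exactly by largest remainder and shuffled;
* 400 genes: every promoter-state region gets a TSS whose core-promoter
  window lies inside the region; surplus TSSs go inside non-enhancer
  regions, where a core promoter cannot change any label;
* mark peaks coincide exactly with their regions (all noise knobs are
  zero), so classification recovery is exact by construction — verified,
  not assumed, by an internal consistency check at generation time and by
  `verify_truth()` on the written files;
* TF groups MYC (200 peaks; placement 30% active promoter, 26% active
  enhancer, 6/8/10/20% elsewhere; motif rate 0.6) and WDR5 (200 peaks;
  11%/3%/8/13/15/50%; motif rate 0.3), emulating the qualitative
  genome-wide marginals reported for these factors; placements are exact
  allocations over distinct regions, so recovered proportions equal
  planted ones with zero tolerance. Joint-region composition is emergent,
  not planted;
* planted motifs are consensus words written at the peak summit
  (sampling from the PFM columns is available as `plant_mode = "sample"`);
* POL II per-state rates (.86, .16, .06, .03, .001, .05) — Bernoulli per
  region, so occupancy recovery is within binomial noise;
* reads: Poisson(rate·width) per region with uniform placement, rates
  (.2, .05, .02, .01, .002, .01) reads/bp — active promoters 10-fold
  above poised ones.

What the generator does *not* emulate: repeat structure, CpG islands,
GC-heterogeneous backgrounds, mark-peak boundary noise, dropout or
spurious peaks, fragment-length or sequencing-error models, and realistic
joint TF co-binding correlation. Passing recovery tests therefore
demonstrates the correctness of the computational chain under its own
model assumptions — they say nothing about the biological validity of the
state definitions on real chromatin, and real-data proportions will
differ from the planted ones.

## 6. Numerical choices and degenerate inputs

* DP grid ε = 0.01 bits by default; the DP is compared against exhaustive
  enumeration of all 4ᵂ words (same grid) to < 10⁻⁶ at ε = 0.001 for
  W ≤ 8 in the test suite. Problem sizes throughout the tests (500×500
  interval instances, 500-window enrichment runs over 20 seeds, 100
  expression replicates at n = 200 per group) were chosen as the smallest
  sizes at which the statistical assertions have comfortable power.
* Fisher p via the hypergeometric tail (`phyper`), checked against both
  direct binomial-coefficient enumeration (all tables with margins ≤ 30,
  < 10⁻¹²) and `fisher.test(alternative = "greater")`.
* Degenerate enrichment tables (no windows, all/no hits) warn and return
  p = 1 rather than erroring; identical expression groups likewise.
* Background-region sampling is uniform over all allowed start positions
  (gap-weighted direct sampling, no rejection loop), reproducible under a
  seed, and errors when the excluded set leaves no room.
* All pipeline randomness flows from one master seed; background sampling
  uses `seed + 1` so that re-running a stage in isolation reproduces the
  run. Determinism is byte-level: two runs with one seed produce identical
  report files.
* `sample()`-based allocation is guarded against R's scalar-`x`
  `sample(x)` pitfall (`sample.int` on index vectors throughout).

## 7. Known limitations

* The six-state rule set is deliberately minimal; no HMM/segmentation
  model (ChromHMM-style) is provided or intended.
* No BAM parsing: reads arrive as intervals in BED. No peak calling: peak
  files are consumed as given.
* The shipped ASH2L-like matrix is a synthetic placeholder (the published
  matrix is not redistributed); supply a real JASPAR file for serious use.
* One motif per pipeline run; run the pipeline per matrix for several.
* Enrichment backgrounds are not GC-matched; on GC-biased real genomes
  this inflates enrichment of GC-rich motifs relative to a matched
  background.
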