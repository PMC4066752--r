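# peakstates

Genome-wide ChIP-seq peak sets only become interpretable once they are placed
in their chromatin context: is a transcription-factor peak sitting on an
active promoter, a distal enhancer, a bivalent (poised) promoter, or in
closed chromatin — and does that placement line up with sequence motifs and
with transcription? `peakstates` is an R package for exactly this style of
integrative analysis, built for regulatory genomicists working with
histone-mark, transcription-factor and RNA polymerase II peak files plus
RNA-seq read intervals. It was developed around the MYC/WDR5 biology of
KMT2 (MLL/SET1) methyltransferase complexes, but every input is a generic
BED/narrowPeak/FASTA file.

## What it computes

**1. Regulatory chromatin states.** Loci are classified into six mutually
exclusive states from four histone-mark peak sets and core-promoter windows
(the 200 bp upstream of each TSS):

| state | rule |
|---|---|
| active promoter | H3K4me3 ∧ H3K27ac ∧ core-promoter overlap |
| poised promoter | H3K4me3 ∧ H3K27me3 (bivalent chromatin) |
| active enhancer | H3K4me1 ∧ H3K27ac, ≥ margin from core promoters |
| poised enhancer | H3K4me1, no H3K27ac, no H3K4me3, distal |
| closed | H3K27me3 only |
| other | none of the above |

Rules are evaluated in a fixed, configurable precedence order; TF peak
groups (and the joint regions carrying both of two factors) are tabulated
against the states, and POL II occupancy is measured per state.

**2. Motif enrichment with an exact score threshold.** Peak summits are
extended ±125 bp and scanned on both strands with a log2-odds PWM. The null
distribution of the score S of a background word is computed *exactly* by
dynamic programming — per-column score distributions under the background
model are convolved on an ε-bit grid — and the bit-score cutoff t is the
smallest support score with

&nbsp;&nbsp;&nbsp;&nbsp;P(S ≥ t) ≤ α,&nbsp;&nbsp;α = 10⁻⁴ per window position.

Peaks with ≥ 1 hit are compared against length-matched random genomic
regions with a one-sided Fisher exact test and a two-proportion z test.

**3. Expression linkage.** RNA reads are counted in summit ±1000 bp windows
of promoter-proximal peaks, normalized to reads per kbp, and compared
between peak groups with a one-sided Wilcoxon rank-sum test (Welch t on
log10 values as secondary).

**4. Synthetic data with planted truth.** `generate_dataset()` emits a
complete toy dataset (genome FASTA, TSS BED, mark/TF/POL II narrowPeaks,
reads BED, JASPAR motif, truth TSVs) in which states, motif occurrences and
read rates are planted, so every stage has an exact parameter-recovery test.

## Worked example

```r
library(peakstates)

cfg <- synthetic_config(seed = 42)          # default study conditions
ds  <- generate_dataset(cfg, "demo_data")

pwm <- pfm_to_pwm(ebox_pfm())               # synthetic width-8 E-box
d   <- exact_null_distribution(pwm, eps = 0.01)
thr <- threshold_for_fpr(d, alpha = 1e-4)
sprintf("threshold: %.2f bits (tail %.3g)", thr, score_tail(d, thr))
#> "threshold: 12.47 bits (tail 4.58e-05)"
```

The threshold is the smallest grid score whose exact null tail drops under
α; scoring windows at ≥ 12.47 bits gives a per-position false-positive rate
of 4.6 × 10⁻⁵.

```r
res <- run_pipeline(list(
  genome_fasta = ds$paths$genome_fasta, chrom_sizes = ds$paths$chrom_sizes,
  tss_bed = ds$paths$tss_bed,
  marks = list(H3K4me3 = ds$paths$H3K4me3, H3K4me1 = ds$paths$H3K4me1,
               H3K27ac = ds$paths$H3K27ac, H3K27me3 = ds$paths$H3K27me3),
  pol2 = ds$paths$POL2,
  tf_peaks = list(MYC = ds$paths$MYC, WDR5 = ds$paths$WDR5),
  reads_bed = ds$paths$reads_bed, motif_jaspar = ds$paths$motif_jaspar,
  seed = 42), "demo_report")

res$motif_enrichment[, c("group", "n", "hits", "proportion",
                         "bg_proportion", "fisher_p", "z_p")]
#>     group   n hits proportion bg_proportion     fisher_p          z_p
#>       MYC 200  128       0.64    0.02500000 6.829159e-45 3.002897e-39
#>      WDR5 200   90       0.45    0.02500000 1.102326e-26 8.683721e-24
#>  MYC+WDR5  68   51       0.75    0.02941176 4.766459e-20 3.476991e-18
```

64% of MYC peak windows contain an E-box at the exact threshold versus 2.5%
of random background windows (planted rate 60% plus the analytic null rate);
enrichment is decisive by both tests. The state table recovers the planted
placement proportions exactly (MYC: 30% active promoters, 26% active
enhancers), POL II occupancy of active promoters comes out at 90% (planted
rate 0.86, n = 120), and promoter-proximal MYC windows are significantly
higher expressed than WDR5 ones (rank-sum p = 1.5 × 10⁻⁵, mean
reads-per-kbp ratio 2.4):

```r
res$expression_comparisons[, c("group", "median", "median_ref",
                               "mean_ratio", "wilcox_p")]
#>     group    median median_ref mean_ratio     wilcox_p
#>       MYC 55.972014   3.498251   2.371714 0.0000146587
#>  MYC+WDR5  3.498251   3.498251   1.312640 0.4311624811
```

A thin CLI wrapper is installed at `inst/scripts/run-pipeline.R`
(`Rscript run-pipeline.R --config run.yaml --out report/`).

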