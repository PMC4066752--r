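# RNA read quantification in summit-centered windows, size normalization,
# promoter-proximal restriction and between-group expression comparison.

#' Count reads overlapping each window
#'
#' A read is counted for a window iff they share at least one base; a read
#' overlapping k windows counts once in each.
#'
#' @param windows GRanges of windows.
#' @param reads GRanges of read intervals.
#' @return Integer vector of counts, one per window.
#' @export
count_reads <- function(windows, reads) {
  countOverlaps(windows, reads, ignore.strand = TRUE)
}

#' Reads per kilobase of window
#'
#' @param counts Integer counts per window.
#' @param windows GRanges (widths must be positive).
#' @return `counts * 1000 / width(windows)`.
#' @export
reads_per_kbp <- function(counts, windows) {
  w <- width(windows)
  if (any(w <= 0)) stop("window widths must be > 0")
  counts * 1000 / w
}

#' Per-window expression table
#'
#' @param windows GRanges of (summit-extended) windows.
#' @param reads GRanges of read intervals.
#' @param offset Pseudo-value added before the log10 transform so
#'   zero-count windows stay finite (default 0.1).
#' @return data.frame with `chrom`, `start` (0-based), `end`, `count`,
#'   `rpk`, `log_rpk`.
#' @export
expression_table <- function(windows, reads, offset = 0.1) {
  counts <- count_reads(windows, reads)
  rpk <- reads_per_kbp(counts, windows)
  data.frame(chrom = as.character(seqnames(windows)),
             start = start(windows) - 1L, end = end(windows),
             count = counts, rpk = rpk, log_rpk = log10(rpk + offset))
}

#' Restrict peaks to promoter-proximal ones
#'
#' Keeps peaks whose interval overlaps at least one core-promoter window
#' (the 200 bp upstream of a TSS; see [upstream_window()]).
#'
#' @param peaks GRanges.
#' @param core_promoters GRanges of core-promoter windows.
#' @return Subset of `peaks`.
#' @export
promoter_proximal <- function(peaks, core_promoters) {
  members_overlapping(peaks, core_promoters)
}

#' Compare expression between two groups of windows
#'
#' Primary test: one-sided Wilcoxon rank-sum on reads-per-kbp (alternative:
#' group `a` greater). Secondary: one-sided Welch t test on
#' `log10(rpk + offset)`. Also reports medians, the mean ratio and the
#' rank-biserial effect size.
#'
#' @param a,b Numeric vectors of reads-per-kbp values (length >= 2 each).
#' @param offset Log offset (default 0.1).
#' @param alternative Direction for `a` vs `b` (default `"greater"`).
#' @return List with `n_a`, `n_b`, `median_a`, `median_b`, `mean_ratio`,
#'   `rank_biserial`, `wilcox_p`, `welch_p`.
#' @export
compare_expression <- function(a, b, offset = 0.1,
                               alternative = "greater") {
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 values")
  degenerate <- length(unique(c(a, b))) == 1
  if (degenerate) {
    warning("all values identical; tests are uninformative, p = 1")
    wp <- 1; tp <- 1; U <- length(a) * length(b) / 2
  } else {
    wt <- suppressWarnings(wilcox.test(a, b, alternative = alternative,
                                       exact = FALSE))
    wp <- wt$p.value
    U <- unname(wt$statistic)
    tp <- tryCatch(
      t.test(log10(a + offset), log10(b + offset),
             alternative = alternative)$p.value,
      error = function(e) NA_real_)
  }
  list(n_a = length(a), n_b = length(b),
       median_a = stats::median(a), median_b = stats::median(b),
       mean_ratio = mean(a) / mean(b),
       rank_biserial = 2 * U / (length(a) * length(b)) - 1,
       wilcox_p = wp, welch_p = tp)
}

#' Simulate reads over windows at a per-bp rate
#'
#' Draws a Poisson(`rate * width`) read count per window and places reads of
#' the given length uniformly inside each window (windows shorter than the
#' read length get reads clipped to the window).
#'
#' @param windows GRanges.
#' @param rate Expected reads per bp of window.
#' @param read_length Read length in bp (default 36).
#' @return GRanges of reads.
#' @export
simulate_reads <- function(windows, rate, read_length = 36) {
  if (rate < 0) stop("rate must be >= 0")
  counts <- rpois(length(windows), rate * width(windows))
  idx <- rep(seq_along(windows), counts)
  if (!length(idx)) return(GRanges(seqinfo = seqinfo(windows)))
  lo <- start(windows)[idx]
  hi <- pmax(end(windows)[idx] - read_length + 1L, lo)
  s <- lo + floor(runif(length(idx)) * (hi - lo + 1L))
  e <- pmin(s + read_length - 1L, end(windows)[idx])
  GRanges(seqnames(windows)[idx], IRanges(s, e),
          seqinfo = seqinfo(windows))
}
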