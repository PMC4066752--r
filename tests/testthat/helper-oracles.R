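# Fixtures and independent brute-force oracles used across the suite.
# Oracles deliberately avoid the code paths they check.

suppressPackageStartupMessages({
  library(GenomicRanges)
})

# GRanges from BED-style 0-based half-open coordinates.
gr0 <- function(chrom, start0, end0, strand = "*", layout = NULL) {
  g <- GRanges(chrom, IRanges(start0 + 1L, end0), strand = strand)
  if (!is.null(layout)) {
    GenomeInfoDb::seqlevels(g) <- GenomeInfoDb::seqlevels(layout)
    GenomeInfoDb::seqinfo(g) <- layout
  }
  g
}

toy_layout <- genome_layout(c(chr1 = 10000, chr2 = 10000))

with_summit0 <- function(gr, summit0) {
  mcols(gr)$summit <- as.integer(summit0 + 1L)
  gr
}

# O(n*m) all-pairs overlap oracle (half-open logic on 0-based coords).
brute_members_overlapping <- function(query, subject) {
  qs <- start(query) - 1L; qe <- end(query)
  ss <- start(subject) - 1L; se <- end(subject)
  qc <- as.character(seqnames(query)); sc <- as.character(seqnames(subject))
  keep <- vapply(seq_along(query), function(i)
    any(qc[i] == sc & qs[i] < se & ss < qe[i]), TRUE)
  query[keep]
}

random_intervals <- function(n, layout, max_width = 200) {
  chroms <- GenomeInfoDb::seqlevels(layout)
  lens <- GenomeInfoDb::seqlengths(layout)
  ci <- sample(seq_along(chroms), n, replace = TRUE)
  w <- sample.int(max_width, n, replace = TRUE)
  s1 <- vapply(seq_len(n), function(i)
    sample.int(lens[ci[i]] - w[i], 1), 1L)
  GRanges(chroms[ci], IRanges(s1, width = w), seqinfo = layout)
}

# Certain width-3 PWM (consensus CAC, prob-1 columns, uniform bg, pc = 0):
# every consensus base scores 2 bits, every mismatch -Inf.
certain_pfm3 <- function() {
  pfm(cbind(c(0, 4, 0, 0), c(4, 0, 0, 0), c(0, 4, 0, 0)), name = "CAC3")
}
certain_pwm3 <- function() pfm_to_pwm(certain_pfm3(), pseudocount = 0)

# Certain width-6 E-box core (CACGTG), for palindromic-scan tests.
certain_ebox6 <- function() {
  one <- function(b) { v <- rep(0, 4); v[match(b, c("A","C","G","T"))] <- 4; v }
  pfm_to_pwm(pfm(vapply(c("C","A","C","G","T","G"), one, numeric(4)),
                 name = "EBOX6"), pseudocount = 0)
}

random_pfm <- function(w, max_count = 50) {
  pfm(matrix(sample.int(max_count, 4 * w, replace = TRUE), nrow = 4),
      name = sprintf("rnd%d", w))
}

random_background <- function() {
  p <- runif(4, 0.1, 0.4)
  p / sum(p)
}

# Exhaustive-enumeration oracle for the null score distribution: every one
# of the 4^W words, scored with the same per-column epsilon-grid rounding
# the distribution contract specifies, weighted by the background.
enum_null_grid <- function(pwm, eps) {
  m <- unclass(pwm)
  bg <- attr(pwm, "background")
  k <- round(m / eps)
  w <- ncol(k)
  words <- as.matrix(expand.grid(rep(list(1:4), w)))
  score_k <- matrix(k[cbind(as.vector(words),
                            rep(seq_len(w), each = nrow(words)))],
                    nrow = nrow(words))
  total_k <- rowSums(score_k)
  logp <- matrix(log(bg)[as.vector(words)], nrow = nrow(words))
  p <- exp(rowSums(logp))
  fin <- is.finite(total_k)
  agg <- rowsum(p[fin], total_k[fin])
  ks <- as.numeric(rownames(agg))
  ord <- order(ks)
  list(score = ks[ord] * eps, prob = as.numeric(agg)[ord],
       p_impossible = sum(p[!fin]))
}

enum_tail <- function(enum, t) sum(enum$prob[enum$score >= t - 1e-9])

# Direct hypergeometric enumeration of the one-sided Fisher p via binomial
# coefficients (no phyper, no fisher.test).
fisher_enum <- function(k1, n1, k2, n2) {
  K <- k1 + k2; N <- n1 + n2
  ks <- max(k1, K - n2):min(n1, K)
  ks <- ks[ks >= k1]
  if (!length(ks)) return(0)
  sum(exp(lchoose(n1, ks) + lchoose(n2, K - ks) - lchoose(N, K)))
}

# Random i.i.d. sequence under a base composition.
random_seq <- function(len, bg = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE, prob = bg),
        collapse = "")
}

make_run_config <- function(ds, seed = 1, ...) {
  tf <- Filter(Negate(is.null),
               list(MYC = ds$paths$MYC, WDR5 = ds$paths$WDR5))
  c(list(genome_fasta = ds$paths$genome_fasta,
         chrom_sizes = ds$paths$chrom_sizes,
         tss_bed = ds$paths$tss_bed,
         marks = list(H3K4me3 = ds$paths$H3K4me3,
                      H3K4me1 = ds$paths$H3K4me1,
                      H3K27ac = ds$paths$H3K27ac,
                      H3K27me3 = ds$paths$H3K27me3),
         pol2 = ds$paths$POL2,
         tf_peaks = tf,
         reads_bed = ds$paths$reads_bed,
         motif_jaspar = ds$paths$motif_jaspar,
         seed = seed),
    list(...))
}
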