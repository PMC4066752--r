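# PWM construction, both-strand scanning of summit-centered windows, the
# exact null score distribution by dynamic programming (the basis of the
# bit-score cutoff at a fixed per-window false-positive rate), matched
# background sampling, and enrichment statistics.

#' Read a position frequency matrix in JASPAR text format
#'
#' Expects a `>ID name` header line followed by four rows
#' `A [ n1 n2 ... ]` ... `T [ ... ]` of equal length.
#'
#' @param path File path.
#' @return A `pfm` object: list with `name` and a 4 x W `counts` matrix
#'   (rows A, C, G, T).
#' @export
read_jaspar <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  header <- grep("^>", lines)
  if (length(header) != 1)
    stop("expected exactly one '>' header line in ", basename(path))
  id <- sub("^>\\s*", "", lines[header])
  rows <- lines[-header]
  base <- toupper(sub("^([A-Za-z]).*$", "\\1", rows))
  if (!setequal(base, DNA_BASES) || length(rows) != 4)
    stop("expected exactly one count row per base A/C/G/T in ",
         basename(path))
  counts <- lapply(rows, function(r) {
    nums <- gsub("[][]", " ", sub("^[A-Za-z]", "", r))
    as.numeric(strsplit(trimws(nums), "\\s+")[[1]])
  })
  names(counts) <- base
  w <- unique(lengths(counts))
  if (length(w) != 1)
    stop("count rows have unequal lengths in ", basename(path))
  mat <- do.call(rbind, counts[DNA_BASES])
  pfm(mat, name = id)
}

#' Construct a position frequency matrix
#'
#' @param counts 4 x W nonnegative matrix, rows in A, C, G, T order.
#' @param name Motif identifier.
#' @return A `pfm` object.
#' @export
pfm <- function(counts, name = "motif") {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4) stop("a PFM needs 4 rows (A, C, G, T)")
  if (ncol(counts) < 1) stop("a PFM needs at least one column")
  if (any(counts < 0) || any(colSums(counts) <= 0))
    stop("counts must be nonnegative with positive column sums")
  dimnames(counts) <- list(DNA_BASES, NULL)
  structure(list(name = name, counts = counts), class = "pfm")
}

#' Write a PFM in JASPAR text format
#' @param x A `pfm`.
#' @param path Output path.
#' @export
write_jaspar <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0(">", x$name), con)
  for (b in DNA_BASES)
    writeLines(sprintf("%s [ %s ]", b,
                       paste(format(x$counts[b, ], trim = TRUE),
                             collapse = " ")), con)
  invisible(path)
}

#' Log2-odds position weight matrix from a PFM
#'
#' Entry for base `b` at column `j` is
#' `log2(((count + pseudocount * bg_b) / (colsum + pseudocount)) / bg_b)`
#' in bits. With `pseudocount = 0`, zero counts give `-Inf`.
#'
#' @param x A `pfm`.
#' @param background Base probabilities (A, C, G, T); must be positive and
#'   sum to 1.
#' @param pseudocount Total pseudocount distributed by the background
#'   (default 0.8, common JASPAR practice).
#' @return A `pwm` object: 4 x W numeric matrix with attributes
#'   `background`, `pseudocount`, `name`.
#' @export
pfm_to_pwm <- function(x, background = rep(0.25, 4), pseudocount = 0.8) {
  stopifnot(is(x, "pfm"))
  if (length(background) != 4 || any(background <= 0))
    stop("background must be 4 strictly positive probabilities")
  if (abs(sum(background) - 1) > 1e-9)
    stop("background probabilities must sum to 1")
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  counts <- x$counts
  csum <- rep(colSums(counts), each = 4)
  p <- (counts + pseudocount * background) / (csum + pseudocount)
  m <- log2(p / background)
  rownames(m) <- DNA_BASES
  structure(m, background = stats::setNames(background, DNA_BASES),
            pseudocount = pseudocount, name = x$name, class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM '%s': width %d, max score %.3f bits\n",
              attr(x, "name"), ncol(x), pwm_max_score(x)))
  print(unclass(x)[, , drop = FALSE])
  invisible(x)
}

#' Width of a PWM/PFM
#' @param x A `pwm` or `pfm`.
#' @return Number of columns W.
#' @export
pwm_width <- function(x) if (is(x, "pfm")) ncol(x$counts) else ncol(x)

#' Maximum attainable PWM score (bits)
#' @param x A `pwm`.
#' @return Sum over columns of the best per-column score.
#' @export
pwm_max_score <- function(x) sum(apply(unclass(x), 2, max))

seq_to_idx <- function(seq) {
  idx <- match(strsplit(toupper(seq), "")[[1]], DNA_BASES)
  idx  # NA for N and other ambiguity codes
}

#' Score a single window of motif width
#'
#' Sum of per-position PWM entries in bits; any non-ACGT base yields `-Inf`.
#'
#' @param pwm A `pwm`.
#' @param seq String of length exactly `pwm_width(pwm)`.
#' @return Score in bits.
#' @export
score_window <- function(pwm, seq) {
  w <- pwm_width(pwm)
  idx <- seq_to_idx(seq)
  if (length(idx) != w)
    stop("sequence length ", length(idx), " != motif width ", w)
  if (anyNA(idx)) return(-Inf)
  sum(unclass(pwm)[cbind(idx, seq_len(w))])
}

# Scores at every offset of one strand; NA bases propagate -Inf.
scan_scores <- function(pwm, idx) {
  w <- ncol(pwm)
  n <- length(idx) - w + 1L
  if (n < 1L) return(numeric(0))
  s <- numeric(n)
  m <- unclass(pwm)
  bad <- rep(FALSE, n)
  for (j in seq_len(w)) {
    ij <- idx[j:(j + n - 1L)]
    bad <- bad | is.na(ij)
    v <- m[, j][ij]
    v[is.na(v)] <- 0
    s <- s + v
  }
  s[bad] <- -Inf
  s
}

revcomp_str <- function(seq) {
  as.character(reverseComplement(DNAStringSet(seq)))
}

#' Scan a region on both strands
#'
#' Slides the PWM over the forward sequence and its reverse complement.
#' Offsets are 0-based region coordinates of the motif's leftmost base on the
#' forward strand. Ties between equal scores are broken by smaller offset,
#' then `+` strand.
#'
#' @param pwm A `pwm`.
#' @param seq Region sequence (A/C/G/T/N string).
#' @param threshold Bit-score cutoff for reported `hits`; `NULL` reports only
#'   the best hit. `Inf` (the unattainable sentinel) yields no hits.
#' @param strand_mode `"both"` (default), `"forward"` or `"reverse"`.
#' @return List with `best` (1-row data.frame `offset`, `strand`, `score`,
#'   or 0-row if the region is shorter than the motif) and `hits` (all
#'   positions scoring >= threshold, same columns, sorted by score
#'   descending with the tie-break above).
#' @export
scan_region <- function(pwm, seq, threshold = NULL,
                        strand_mode = c("both", "forward", "reverse")) {
  strand_mode <- match.arg(strand_mode)
  w <- pwm_width(pwm)
  L <- nchar(seq)
  empty <- data.frame(offset = integer(0), strand = character(0),
                      score = numeric(0))
  if (L < w) {
    warning("region length ", L, " shorter than motif width ", w)
    return(list(best = empty, hits = empty))
  }
  cand <- list()
  if (strand_mode != "reverse") {
    s <- scan_scores(pwm, seq_to_idx(seq))
    cand$fwd <- data.frame(offset = seq_along(s) - 1L, strand = "+",
                           score = s)
  }
  if (strand_mode != "forward") {
    s <- scan_scores(pwm, seq_to_idx(revcomp_str(seq)))
    # offset i on the reverse complement covers forward bases
    # [L - w - i, L - i) -> leftmost forward base L - w - i
    cand$rev <- data.frame(offset = L - w - (seq_along(s) - 1L),
                           strand = "-", score = s)
  }
  all <- do.call(rbind, cand)
  ord <- order(-all$score, all$offset, all$strand)
  all <- all[ord, , drop = FALSE]
  rownames(all) <- NULL
  hits <- if (is.null(threshold)) empty else
    all[is.finite(all$score) & all$score >= threshold, , drop = FALSE]
  rownames(hits) <- NULL
  list(best = all[1, , drop = FALSE], hits = hits)
}

#' Exact null score distribution by dynamic programming
#'
#' Computes the distribution of the PWM score of a random width-W word drawn
#' i.i.d. from the PWM's background model. Per-column scores are rounded to
#' an epsilon grid and the per-column 4-outcome distributions are convolved
#' column by column. `-Inf` entries (possible with pseudocount 0) send their
#' probability mass to a dedicated impossible bin excluded from the grid.
#'
#' The tail function is `P(S >= t, S finite)`; it is deliberately not
#' renormalized when impossible mass exists, so it is directly the
#' per-window-position false-positive probability of a score cutoff.
#'
#' @param pwm A `pwm` (its `background` attribute is the null model).
#' @param eps Grid bin width in bits (default 0.01).
#' @return A `score_distribution`: list with `eps`, `score` (ascending grid
#'   support), `prob`, `tail`, `p_impossible`.
#' @export
exact_null_distribution <- function(pwm, eps = 0.01) {
  if (eps <= 0) stop("eps must be > 0")
  bg <- attr(pwm, "background")
  m <- unclass(pwm)
  k <- round(m / eps)  # integer grid per entry; -Inf stays -Inf
  w <- ncol(k)
  # dense vector over the reachable grid range, plus impossible mass
  finite_min <- apply(k, 2, function(col) min(col[is.finite(col)]))
  finite_max <- apply(k, 2, function(col) max(col[is.finite(col)]))
  if (any(!is.finite(finite_min)))
    stop("a PWM column has no finite score under this background")
  lo <- sum(finite_min)
  hi <- sum(finite_max)
  d <- numeric(hi - lo + 1L)
  off <- 0L         # current distribution spans grid offsets cum_lo..;
  cum_lo <- 0L      # d[i] = P(K = cum_lo + i - 1), within first j columns
  d[1] <- 1
  len <- 1L
  p_imp <- 0
  for (j in seq_len(w)) {
    col <- k[, j]
    fin <- is.finite(col)
    p_imp <- p_imp + sum(d[seq_len(len)]) * sum(bg[!fin])
    new_lo <- cum_lo + min(col[fin])
    new_len <- len + (max(col[fin]) - min(col[fin]))
    nd <- numeric(new_len)
    for (b in which(fin)) {
      sh <- cum_lo + col[b] - new_lo  # shift of this outcome in new vector
      nd[(sh + 1L):(sh + len)] <- nd[(sh + 1L):(sh + len)] +
        d[seq_len(len)] * bg[b]
    }
    d <- nd
    len <- new_len
    cum_lo <- new_lo
  }
  keep <- d > 0
  score <- (cum_lo + which(keep) - 1L) * eps
  prob <- d[keep]
  structure(list(eps = eps, score = score, prob = prob,
                 tail = rev(cumsum(rev(prob))), p_impossible = p_imp),
            class = "score_distribution")
}

#' @export
print.score_distribution <- function(x, ...) {
  cat(sprintf(paste0("Exact PWM null score distribution: %d support points",
                     " in [%.3f, %.3f] bits (eps = %g)\n"),
              length(x$score), min(x$score), max(x$score), x$eps))
  if (x$p_impossible > 0)
    cat(sprintf("  impossible (-Inf) mass: %.3g\n", x$p_impossible))
  invisible(x)
}

#' Tail probability of a score distribution
#'
#' @param dist A `score_distribution`.
#' @param t Score(s) in bits.
#' @return `P(S >= t, S finite)` for each `t`.
#' @export
score_tail <- function(dist, t) {
  vapply(t, function(ti) {
    i <- which(dist$score >= ti - dist$eps / 2)
    if (!length(i)) 0 else dist$tail[i[1]]
  }, 0)
}

#' Bit-score threshold at a fixed per-window false-positive rate
#'
#' Returns the smallest support score `t` with `tail(t) <= alpha`. If even
#' the maximum attainable score has tail probability above `alpha`, the
#' threshold is unattainable: `Inf` is returned with attribute
#' `unattainable = TRUE`, and scanning at that threshold reports no hits.
#'
#' @param dist A `score_distribution`.
#' @param alpha Per-position type-I error rate, in (0, 1) (default 1e-4).
#' @return Threshold in bits (possibly `Inf`, see above), with attribute
#'   `unattainable`.
#' @export
threshold_for_fpr <- function(dist, alpha = 1e-4) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  ok <- which(dist$tail <= alpha)
  if (!length(ok))
    return(structure(Inf, unattainable = TRUE))
  structure(dist$score[ok[1]], unattainable = FALSE)
}

#' Sample random background regions
#'
#' Draws fixed-width regions uniformly over every start position at which a
#' region fits inside a chromosome without overlapping the excluded set
#' (regions may overlap each other, as for random genomic background draws).
#' Sampling is reproducible under `seed`.
#'
#' @param n Number of regions.
#' @param width Region width in bp.
#' @param layout A Seqinfo layout.
#' @param excluded GRanges that regions must not overlap (default none).
#' @param seed Optional integer seed.
#' @return GRanges of `n` regions.
#' @export
sample_background_regions <- function(n, width, layout,
                                      excluded = GRanges(), seed = NULL) {
  if (n < 1) stop("n must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  # allowed gaps: chromosome space not covered by the excluded set
  whole <- GRanges(seqlevels(layout), IRanges(1L, seqlengths(layout)),
                   seqinfo = layout)
  excl <- reduce(granges(excluded), ignore.strand = TRUE)
  free <- setdiff(whole, excl, ignore.strand = TRUE)
  free <- free[width(free) >= width]
  room <- width(free) - width + 1
  if (!length(free))
    stop("no room to place background regions of width ", width,
         " outside the excluded set")
  gi <- sample.int(length(free), n, replace = TRUE, prob = room)
  start1 <- start(free)[gi] + floor(runif(n) * room[gi])
  GRanges(seqnames(free)[gi], IRanges(as.integer(start1), width = width),
          seqinfo = layout)
}

#' One-sided Fisher p for a greater first proportion
#'
#' Exact hypergeometric tail `P(X >= k1)` for the 2x2 table
#' `(k1, n1 - k1; k2, n2 - k2)`, identical to
#' `fisher.test(alternative = "greater")`. Vectorized.
#'
#' @param k1,n1 Hits and total in the first group.
#' @param k2,n2 Hits and total in the second group.
#' @return P-value(s).
#' @export
fisher_p_greater <- function(k1, n1, k2, n2) {
  phyper(k1 - 1, k1 + k2, n1 + n2 - k1 - k2, n1, lower.tail = FALSE)
}

#' Two-proportion z test (pooled), one-sided greater
#' @inheritParams fisher_p_greater
#' @return List with `z` and `p`.
#' @export
two_prop_z <- function(k1, n1, k2, n2) {
  p_pool <- (k1 + k2) / (n1 + n2)
  se <- sqrt(p_pool * (1 - p_pool) * (1 / n1 + 1 / n2))
  z <- if (se == 0) 0 else (k1 / n1 - k2 / n2) / se
  list(z = z, p = pnorm(z, lower.tail = FALSE))
}

#' Does each sequence contain at least one motif hit?
#'
#' @param seqs Character vector of window sequences.
#' @param pwm A `pwm`.
#' @param threshold Bit-score cutoff (possibly `Inf`).
#' @return Logical vector.
#' @export
has_motif_hit <- function(seqs, pwm, threshold) {
  if (is.infinite(threshold)) return(rep(FALSE, length(seqs)))
  vapply(seqs, function(s) {
    if (nchar(s) < pwm_width(pwm)) return(FALSE)
    sc <- scan_region(pwm, s)$best$score
    length(sc) > 0 && is.finite(sc) && sc >= threshold
  }, TRUE, USE.NAMES = FALSE)
}

#' Motif enrichment of peak windows over background windows
#'
#' Counts windows containing at least one hit at the threshold
#' (presence/absence per window, not hit counts) in the peak and background
#' sets, then reports the one-sided Fisher exact p (proportion of peak
#' windows with a site greater than background) and a one-sided pooled
#' two-proportion z test.
#'
#' @param peak_seqs,bg_seqs Character vectors of window sequences.
#' @param pwm A `pwm`.
#' @param threshold Bit-score cutoff from [threshold_for_fpr()].
#' @return An `enrichment_result` list: `n_peaks`, `peak_hits`, `peak_prop`,
#'   `n_bg`, `bg_hits`, `bg_prop`, `fisher_p`, `z`, `z_p`,
#'   `threshold_bits`.
#' @export
enrichment_test <- function(peak_seqs, bg_seqs, pwm, threshold) {
  n1 <- length(peak_seqs); n2 <- length(bg_seqs)
  if (n1 == 0 || n2 == 0) {
    warning("empty window set: enrichment undefined, p = 1")
    return(structure(list(n_peaks = n1, peak_hits = 0L, peak_prop = NA_real_,
                          n_bg = n2, bg_hits = 0L, bg_prop = NA_real_,
                          fisher_p = 1, z = 0, z_p = 1,
                          threshold_bits = as.numeric(threshold)),
                     class = "enrichment_result"))
  }
  k1 <- sum(has_motif_hit(peak_seqs, pwm, threshold))
  k2 <- sum(has_motif_hit(bg_seqs, pwm, threshold))
  if (k1 + k2 == 0 || k1 + k2 == n1 + n2)
    warning("degenerate 2x2 table (all or no windows hit)")
  zt <- two_prop_z(k1, n1, k2, n2)
  structure(list(n_peaks = n1, peak_hits = as.integer(k1),
                 peak_prop = k1 / n1,
                 n_bg = n2, bg_hits = as.integer(k2), bg_prop = k2 / n2,
                 fisher_p = fisher_p_greater(k1, n1, k2, n2),
                 z = zt$z, z_p = zt$p,
                 threshold_bits = as.numeric(threshold)),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(paste0("Motif enrichment: %d/%d peak windows (%.1f%%) vs ",
                     "%d/%d background (%.1f%%)\n",
                     "  Fisher one-sided p = %.3g; z = %.2f (p = %.3g); ",
                     "threshold %.3f bits\n"),
              x$peak_hits, x$n_peaks, 100 * x$peak_prop,
              x$bg_hits, x$n_bg, 100 * x$bg_prop,
              x$fisher_p, x$z, x$z_p, x$threshold_bits))
  invisible(x)
}
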