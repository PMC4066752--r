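# Rule-based classification of loci into six regulatory chromatin states from
# histone-mark peak sets, plus the relation of TF peak groups (and their joint
# regions) to those states and to POL II occupancy.

#' Bundle histone-mark (and optional POL II) peak sets
#'
#' @param H3K4me3,H3K4me1,H3K27ac,H3K27me3 GRanges peak sets, one per mark.
#' @param POL2 Optional GRanges of RNA polymerase II peaks.
#' @return A named list of class `mark_collection`.
#' @export
mark_collection <- function(H3K4me3, H3K4me1, H3K27ac, H3K27me3, POL2 = NULL) {
  marks <- list(H3K4me3 = H3K4me3, H3K4me1 = H3K4me1,
                H3K27ac = H3K27ac, H3K27me3 = H3K27me3)
  if (!is.null(POL2)) marks$POL2 <- POL2
  ok <- vapply(marks, function(x) is(x, "GRanges"), TRUE)
  if (!all(ok)) stop("all mark peak sets must be GRanges")
  structure(marks, class = "mark_collection")
}

# Logical evidence matrix: per locus, overlap with each mark and with the
# (margin-extended) core-promoter windows.
state_evidence <- function(loci, marks, core_promoters, margin) {
  near <- suppressWarnings(trim(core_promoters + margin))
  list(
    k4me3 = overlapsAny(loci, marks$H3K4me3, ignore.strand = TRUE),
    k4me1 = overlapsAny(loci, marks$H3K4me1, ignore.strand = TRUE),
    k27ac = overlapsAny(loci, marks$H3K27ac, ignore.strand = TRUE),
    k27me3 = overlapsAny(loci, marks$H3K27me3, ignore.strand = TRUE),
    at_promoter = overlapsAny(loci, core_promoters, ignore.strand = TRUE),
    distal = !overlapsAny(loci, near, ignore.strand = TRUE)
  )
}

state_rules <- function(ev) {
  list(
    active_promoter = ev$k4me3 & ev$k27ac & ev$at_promoter,
    poised_promoter = ev$k4me3 & ev$k27me3,
    active_enhancer = ev$k4me1 & ev$k27ac & ev$distal,
    # interpretation: a poised enhancer must also lack H3K4me3, otherwise
    # every bivalent promoter with an H3K4me1 peak would shadow the
    # promoter rules under alternative precedence orders
    poised_enhancer = ev$k4me1 & !ev$k27ac & !ev$k4me3 & ev$distal,
    closed = ev$k27me3 & !ev$k4me3 & !ev$k4me1 & !ev$k27ac
  )
}

#' Classify loci into regulatory chromatin states
#'
#' Each locus gets exactly one of the six labels in [STATE_LABELS]. Rules are
#' evaluated in a fixed precedence order and the first match wins:
#' active promoter (H3K4me3 + H3K27ac + core-promoter overlap), poised
#' promoter (H3K4me3 + H3K27me3), active enhancer (H3K4me1 + H3K27ac, distal
#' from core promoters), poised enhancer (H3K4me1, no H3K27ac, no H3K4me3,
#' distal), closed (only H3K27me3 among the four marks), else `other`.
#' "Distal" means at least `margin` bp from every core-promoter window.
#'
#' The `enhancer_first` precedence evaluates the active-enhancer rule before
#' the poised-promoter rule; use [precedence_comparison()] to see which loci
#' change label between the two orders.
#'
#' @param loci GRanges to classify.
#' @param marks A [mark_collection()].
#' @param core_promoters GRanges of core-promoter windows (see
#'   [upstream_window()]).
#' @param margin Distance in bp that enhancers must keep from core promoters
#'   (default 2000).
#' @param precedence `"promoter_first"` (default) or `"enhancer_first"`.
#' @return Factor of labels with levels [STATE_LABELS].
#' @export
classify_loci <- function(loci, marks, core_promoters, margin = 2000,
                          precedence = c("promoter_first", "enhancer_first")) {
  precedence <- match.arg(precedence)
  rules <- state_rules(state_evidence(loci, marks, core_promoters, margin))
  order <- switch(precedence,
    promoter_first = c("active_promoter", "poised_promoter",
                       "active_enhancer", "poised_enhancer", "closed"),
    enhancer_first = c("active_promoter", "active_enhancer",
                       "poised_promoter", "poised_enhancer", "closed"))
  lab <- rep("other", length(loci))
  undecided <- rep(TRUE, length(loci))
  for (r in order) {
    hit <- undecided & rules[[r]]
    lab[hit] <- r
    undecided <- undecided & !hit
  }
  factor(lab, levels = STATE_LABELS)
}

#' Compare classification under both precedence orders
#'
#' Re-runs [classify_loci()] with `promoter_first` and `enhancer_first`
#' precedence and reports every locus whose label differs, so rule-order
#' sensitivity is never silent.
#'
#' @inheritParams classify_loci
#' @return List with `table` (cross-tabulation), `n_differ`, and `differing`
#'   (data.frame of loci with both labels).
#' @export
precedence_comparison <- function(loci, marks, core_promoters, margin = 2000) {
  a <- classify_loci(loci, marks, core_promoters, margin, "promoter_first")
  b <- classify_loci(loci, marks, core_promoters, margin, "enhancer_first")
  differ <- which(a != b)
  list(
    table = table(promoter_first = a, enhancer_first = b),
    n_differ = length(differ),
    differing = data.frame(
      chrom = as.character(seqnames(loci))[differ],
      start = start(loci)[differ] - 1L, end = end(loci)[differ],
      promoter_first = as.character(a)[differ],
      enhancer_first = as.character(b)[differ])
  )
}

#' Regulatory feature regions from mark peaks
#'
#' Candidate loci are the merged union of all mark peaks and core-promoter
#' windows; each merged region is classified and the regions are returned
#' grouped by label.
#'
#' @inheritParams classify_loci
#' @return Named list label -> GRanges (all six labels present, possibly
#'   empty).
#' @export
feature_regions <- function(marks, core_promoters, margin = 2000) {
  pieces <- lapply(marks[setdiff(names(marks), "POL2")], granges)
  cand <- reduce(c(do.call(c, unname(pieces)), granges(core_promoters)),
                 ignore.strand = TRUE)
  lab <- classify_loci(cand, marks, core_promoters, margin)
  stats::setNames(lapply(STATE_LABELS, function(l) cand[lab == l]),
                  STATE_LABELS)
}

#' Joint regions of two peak sets
#'
#' One region per intersection of an overlapping peak pair, merged when
#' intersections themselves overlap. The representative summit is the first
#' `a`-peak summit falling inside the region; if none does, the region
#' midpoint is used and flagged in `summit_imputed`.
#'
#' @param a,b GRanges peak sets; `a` must carry `summit` metadata.
#' @return GRanges of joint regions with `summit` and `summit_imputed`.
#' @export
joint_regions <- function(a, b) {
  hits <- findOverlaps(a, b, ignore.strand = TRUE)
  if (!length(hits)) {
    out <- GRanges(seqinfo = seqinfo(a))
    mcols(out)$summit <- integer(0)
    mcols(out)$summit_imputed <- logical(0)
    return(out)
  }
  inter <- pintersect(granges(a)[queryHits(hits)],
                      granges(b)[subjectHits(hits)], ignore.strand = TRUE)
  strand(inter) <- "*"
  merged <- reduce(inter)
  summit_a <- summit_positions(a)
  # first contributing a-summit inside each merged region
  ov <- findOverlaps(merged, a, ignore.strand = TRUE)
  s <- summit_a[subjectHits(ov)]
  inside <- s >= start(merged)[queryHits(ov)] & s <= end(merged)[queryHits(ov)]
  ov <- ov[inside]
  s <- s[inside]
  summit <- rep(NA_integer_, length(merged))
  first <- !duplicated(queryHits(ov))
  summit[queryHits(ov)[first]] <- s[first]
  imputed <- is.na(summit)
  # 0-based floor midpoint, expressed 1-based
  mid0 <- ((start(merged) - 1L) + end(merged)) %/% 2L
  summit[imputed] <- mid0[imputed] + 1L
  mcols(merged)$summit <- summit
  mcols(merged)$summit_imputed <- imputed
  merged
}

#' Relate TF peak groups to regulatory chromatin states
#'
#' Classifies every peak of every group (by its full interval, or by its
#' summit base with `mode = "summit"`) and tabulates counts and proportions
#' per state.
#'
#' @param groups Named list of GRanges peak sets (e.g. MYC, WDR5, joint
#'   regions).
#' @inheritParams classify_loci
#' @param mode Classify by the peak `"interval"` (default) or its width-1
#'   `"summit"` position.
#' @return data.frame with columns `group`, `label`, `count`, `proportion`;
#'   proportions sum to 1 within each non-empty group.
#' @export
assign_peaks <- function(groups, marks, core_promoters, margin = 2000,
                         mode = c("interval", "summit"),
                         precedence = "promoter_first") {
  mode <- match.arg(mode)
  stopifnot(is.list(groups), !is.null(names(groups)))
  rows <- lapply(names(groups), function(g) {
    peaks <- groups[[g]]
    if (!length(peaks)) {
      warning("group '", g, "' has no peaks; reporting a zero row")
      counts <- stats::setNames(integer(length(STATE_LABELS)), STATE_LABELS)
      props <- rep(0, length(STATE_LABELS))
    } else {
      loci <- if (mode == "summit") {
        s <- summit_positions(peaks)
        GRanges(seqnames(peaks), IRanges(s, s), seqinfo = seqinfo(peaks))
      } else granges(peaks)
      lab <- classify_loci(loci, marks, core_promoters, margin,
                           precedence = precedence)
      counts <- table(lab)
      props <- as.numeric(counts) / length(peaks)
    }
    data.frame(group = g, label = STATE_LABELS,
               count = as.integer(counts), proportion = props)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' POL II occupancy of feature regions
#'
#' Fraction of feature regions per state overlapping at least one POL II
#' peak.
#'
#' @param features Named list label -> GRanges (see [feature_regions()]).
#' @param pol2 GRanges of POL II peaks.
#' @return data.frame with `label`, `n`, `n_pol2`, `fraction`.
#' @export
polii_occupancy <- function(features, pol2) {
  if (is.null(pol2)) stop("POL II peak set is required")
  rows <- lapply(names(features), function(l) {
    f <- features[[l]]
    n_pol2 <- sum(overlapsAny(f, pol2, ignore.strand = TRUE))
    data.frame(label = l, n = length(f), n_pol2 = n_pol2,
               fraction = if (length(f)) n_pol2 / length(f) else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
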