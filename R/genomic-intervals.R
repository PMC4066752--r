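# Interval plumbing: layouts, BED/narrowPeak/chrom.sizes readers and writers,
# overlap queries, summit extension, upstream (core-promoter) windows and
# sequence extraction. On-disk coordinates are BED-style 0-based half-open;
# in memory everything is GRanges (1-based closed).

#' Build a genome layout from chromosome lengths
#'
#' @param lengths Named numeric vector of chromosome lengths in bp.
#' @return A [GenomeInfoDb::Seqinfo] object.
#' @examples
#' genome_layout(c(chr1 = 1e6, chr2 = 5e5))
#' @export
genome_layout <- function(lengths) {
  nm <- names(lengths)
  if (is.null(nm) || any(nm == "") || anyDuplicated(nm))
    stop("chromosome names must be unique and non-empty")
  if (any(!is.finite(lengths)) || any(lengths <= 0) ||
      any(lengths != as.integer(lengths)))
    stop("chromosome lengths must be positive integers")
  Seqinfo(seqnames = nm, seqlengths = as.integer(lengths))
}

#' Read a UCSC chrom.sizes file
#'
#' Two tab-separated columns: chromosome name, length.
#'
#' @param path File path.
#' @return A [GenomeInfoDb::Seqinfo] layout.
#' @export
read_chrom_sizes <- function(path) {
  tab <- read.table(path, sep = "\t", header = FALSE,
                    colClasses = c("character", "integer"))
  genome_layout(stats::setNames(tab[[2]], tab[[1]]))
}

#' Write a layout as a chrom.sizes file
#' @param layout A Seqinfo layout.
#' @param path Output path.
#' @export
write_chrom_sizes <- function(layout, path) {
  write.table(data.frame(seqlevels(layout), seqlengths(layout)),
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

bind_layout <- function(gr, layout) {
  if (is.null(layout)) return(gr)
  if (!all(as.character(seqnames(gr)) %in% seqlevels(layout)))
    stop("interval on a chromosome absent from the layout")
  GenomeInfoDb::seqlevels(gr) <- seqlevels(layout)
  suppressWarnings(seqinfo(gr) <- layout)  # own bounds check below
  bad <- end(gr) > seqlengths(layout)[as.character(seqnames(gr))]
  if (any(bad))
    stop("interval extends beyond chromosome length: record ",
         which(bad)[1])
  gr
}

parse_bed_fields <- function(lines, min_fields, what) {
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < min_fields))
    stop(sprintf("%s: line %d has %d field(s), expected >= %d",
                 what, which(nf < min_fields)[1],
                 nf[which(nf < min_fields)[1]], min_fields))
  fields
}

check_coords <- function(start0, end0, what) {
  bad <- which(is.na(start0) | is.na(end0))
  if (length(bad))
    stop(sprintf("%s: line %d: coordinates do not parse as integers",
                 what, bad[1]))
  bad <- which(start0 < 0 | start0 >= end0)
  if (length(bad))
    stop(sprintf("%s: line %d: invalid interval [%d, %d)",
                 what, bad[1], start0[bad[1]], end0[bad[1]]))
}

#' Read a BED3/BED6 file into a GRanges
#'
#' BED coordinates (0-based half-open) are converted to the 1-based closed
#' GRanges convention. Strand is taken from column 6 when present, else `*`;
#' the `name` column (4) is kept when present.
#'
#' @param path File path (tab-separated, no header).
#' @param layout Optional [GenomeInfoDb::Seqinfo] to bind; coordinates are
#'   checked against chromosome lengths.
#' @return A [GenomicRanges::GRanges].
#' @export
read_bed <- function(path, layout = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(bind_layout(GRanges(), layout))
  fields <- parse_bed_fields(lines, 3L, basename(path))
  chrom <- vapply(fields, `[[`, "", 1L)
  start0 <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end0 <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  check_coords(start0, end0, basename(path))
  nf <- lengths(fields)
  name <- vapply(fields, function(f)
    if (length(f) >= 4L) f[[4L]] else NA_character_, "")
  strand <- vapply(fields, function(f)
    if (length(f) >= 6L) f[[6L]] else "*", "")
  strand[!strand %in% c("+", "-")] <- "*"
  gr <- GRanges(chrom, IRanges(start0 + 1L, end0), strand = strand)
  if (any(nf >= 4L)) mcols(gr)$name <- name
  bind_layout(gr, layout)
}

#' Write a GRanges as BED
#'
#' Emits BED3 when the input carries neither names nor strand, else BED6
#' (missing names become `.`, score column 0).
#'
#' @param gr A GRanges.
#' @param path Output path.
#' @export
write_bed <- function(gr, path) {
  start0 <- start(gr) - 1L
  strand <- as.character(strand(gr))
  has_extra <- !is.null(mcols(gr)$name) || any(strand != "*")
  if (!has_extra) {
    df <- data.frame(as.character(seqnames(gr)), start0, end(gr))
  } else {
    name <- mcols(gr)$name
    if (is.null(name)) name <- rep(".", length(gr))
    name[is.na(name)] <- "."
    strand[strand == "*"] <- "."
    df <- data.frame(as.character(seqnames(gr)), start0, end(gr),
                     name, 0L, strand)
  }
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an ENCODE narrowPeak (BED6+4) file
#'
#' The summit is stored in metadata column `summit` as a 1-based absolute
#' position (`start + offset` in 0-based terms). A summit offset of -1
#' (unknown) is imputed as the interval midpoint and flagged in
#' `summit_imputed`.
#'
#' @param path File path.
#' @param layout Optional Seqinfo layout to bind.
#' @return GRanges with metadata columns `name`, `score`, `signal`,
#'   `summit`, `summit_imputed`.
#' @export
read_narrowpeak <- function(path, layout = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    gr <- GRanges()
    mcols(gr)$summit <- integer(0)
    mcols(gr)$summit_imputed <- logical(0)
    return(bind_layout(gr, layout))
  }
  fields <- parse_bed_fields(lines, 10L, basename(path))
  chrom <- vapply(fields, `[[`, "", 1L)
  start0 <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end0 <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  check_coords(start0, end0, basename(path))
  offset <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 10L)))
  bad <- which(is.na(offset) | offset < -1L)
  if (length(bad))
    stop(sprintf("%s: line %d: summit offset must be an integer >= -1",
                 basename(path), bad[1]))
  bad <- which(offset >= end0 - start0)
  if (length(bad))
    stop(sprintf("%s: line %d: summit offset %d outside %d bp peak",
                 basename(path), bad[1], offset[bad[1]],
                 end0[bad[1]] - start0[bad[1]]))
  imputed <- offset == -1L
  summit0 <- ifelse(imputed, (start0 + end0) %/% 2L, start0 + offset)
  gr <- GRanges(chrom, IRanges(start0 + 1L, end0))
  mcols(gr)$name <- vapply(fields, `[[`, "", 4L)
  mcols(gr)$score <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 7L)))
  mcols(gr)$summit <- as.integer(summit0 + 1L)
  mcols(gr)$summit_imputed <- imputed
  bind_layout(gr, layout)
}

#' Write peaks as narrowPeak
#'
#' @param gr GRanges with a `summit` metadata column (1-based absolute);
#'   optional `name` and `score`.
#' @param path Output path.
#' @export
write_narrowpeak <- function(gr, path) {
  summit <- mcols(gr)$summit
  if (is.null(summit)) stop("peaks lack a 'summit' metadata column")
  name <- mcols(gr)$name
  if (is.null(name)) name <- sprintf("peak_%d", seq_along(gr))
  score <- mcols(gr)$score
  if (is.null(score)) score <- rep(0, length(gr))
  df <- data.frame(as.character(seqnames(gr)), start(gr) - 1L, end(gr),
                   name, 0L, ".", score, -1, -1, summit - start(gr))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Pairwise interval overlap
#'
#' Element-wise test whether `a[i]` and `b[i]` share at least one base
#' (half-open logic; strand ignored).
#'
#' @param a,b GRanges of equal length (or length 1, recycled).
#' @return Logical vector.
#' @export
ranges_overlap <- function(a, b) {
  as.logical(poverlaps(a, b, ignore.strand = TRUE))
}

#' Subset query intervals overlapping any subject interval
#'
#' Returns exactly those `query` ranges sharing >= 1 base with at least one
#' `subject` range, in their original order. Strand is ignored.
#'
#' @param query,subject GRanges.
#' @return Subset of `query`.
#' @export
members_overlapping <- function(query, subject) {
  query[overlapsAny(query, subject, ignore.strand = TRUE)]
}

summit_positions <- function(peaks) {
  summit <- mcols(peaks)$summit
  if (is.null(summit)) stop("peaks lack a 'summit' metadata column")
  if (any(summit < start(peaks) | summit > end(peaks)))
    stop("summit outside its peak interval")
  summit
}

#' Summit-centered windows
#'
#' Extends each peak summit by `flank` bp in both directions. With
#' `include_summit = TRUE` (default) the summit base itself is part of the
#' window, giving width `2*flank + 1`; with `FALSE` the window is
#' `[summit - flank, summit + flank)` of width `2*flank`. Windows are clipped
#' to chromosome bounds when a layout is attached.
#'
#' @param peaks GRanges with `summit` metadata (1-based absolute).
#' @param flank Non-negative flank in bp.
#' @param include_summit Include the summit base (width 2f+1)?
#' @return GRanges of windows carrying the peaks' metadata.
#' @export
extend_about_summit <- function(peaks, flank, include_summit = TRUE) {
  if (flank < 0) stop("flank must be >= 0")
  summit <- summit_positions(peaks)
  upper <- if (include_summit) summit + flank else summit + flank - 1L
  upper <- pmax(upper, summit - flank)  # flank 0, exclusive mode
  gr <- suppressWarnings(GRanges(seqnames(peaks),
                                 IRanges(pmax(summit - flank, 1L), upper),
                                 seqinfo = seqinfo(peaks)))
  gr <- suppressWarnings(trim(gr))
  mcols(gr) <- mcols(peaks)
  gr
}

#' Core-promoter (upstream) windows of TSSs
#'
#' For a plus-strand TSS at 0-based position `t` the window is
#' `[t - width, t)`; for minus strand, `[t + 1, t + 1 + width)`; the TSS base
#' itself is excluded on both strands. Windows are clipped to the chromosome.
#'
#' @param tss Stranded GRanges whose `start` is the TSS position (width-1
#'   ranges, e.g. from a TSS BED).
#' @param width Window width in bp (default 200, the core promoter).
#' @return GRanges of unstranded windows (TSS metadata preserved).
#' @export
upstream_window <- function(tss, width = 200) {
  if (width <= 0) stop("width must be > 0")
  if (any(strand(tss) == "*"))
    stop("TSS entries must be stranded (+ or -)")
  anchor <- GRanges(seqnames(tss), IRanges(start(tss), start(tss)),
                    strand = strand(tss), seqinfo = seqinfo(tss))
  win <- suppressWarnings(promoters(anchor, upstream = width,
                                    downstream = 0))
  mcols(win) <- mcols(tss)
  start(win) <- pmax(start(win), 1L)  # left clip even without a layout
  win <- suppressWarnings(trim(win))
  win <- win[width(win) > 0]
  strand(win) <- "*"
  win
}

#' Read a genome FASTA
#'
#' Thin wrapper over [Biostrings::readDNAStringSet] that uppercases and
#' truncates sequence names at the first whitespace.
#'
#' @param path FASTA file.
#' @return A [Biostrings::DNAStringSet].
#' @export
read_genome_fasta <- function(path) {
  genome <- readDNAStringSet(path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome
}

#' Layout of a loaded genome
#' @param genome DNAStringSet.
#' @return Seqinfo with the sequence lengths.
#' @export
layout_of <- function(genome) {
  genome_layout(stats::setNames(width(genome), names(genome)))
}

#' Fetch region sequences from a genome
#'
#' Returns uppercase A/C/G/T/N strings of length `width(regions)`;
#' minus-strand regions are reverse-complemented.
#'
#' @param regions GRanges.
#' @param genome DNAStringSet covering the regions.
#' @return Character vector of sequences.
#' @export
fetch_sequence <- function(regions, genome) {
  chrom <- as.character(seqnames(regions))
  missing <- setdiff(unique(chrom), names(genome))
  if (length(missing))
    stop("chromosome(s) absent from genome: ", paste(missing, collapse = ", "))
  glen <- stats::setNames(width(genome), names(genome))
  if (any(start(regions) < 1L | end(regions) > glen[chrom]))
    stop("region exceeds chromosome bounds")
  chars <- stats::setNames(toupper(as.character(genome)), names(genome))
  seqs <- substring(chars[chrom], start(regions), end(regions))
  neg <- as.character(strand(regions)) == "-"
  if (any(neg))
    seqs[neg] <- as.character(reverseComplement(DNAStringSet(seqs[neg])))
  unname(seqs)
}
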