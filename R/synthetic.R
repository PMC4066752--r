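# Seeded synthetic-data generator: genome, TSS annotation, histone-mark peaks
# with planted state structure, TF peaks with planted motifs, POL II peaks and
# RNA reads, plus a machine-readable truth table. Emits exactly the formats
# the pipeline consumes, so every stage has a no-download recovery test.

#' Synthetic E-box position frequency matrix
#'
#' A width-8 matrix with a near-certain CACGTG core and weakly informative
#' T/A-preferring flanks (consensus TCACGTGA). Synthetic: constructed for
#' testing, not taken from any motif database. Width 8 keeps a 1e-4
#' per-position false-positive threshold attainable under a uniform
#' background (the minimum word probability 4^-W must not exceed alpha).
#'
#' @return A `pfm`.
#' @export
ebox_pfm <- function() {
  core <- function(b) {
    col <- rep(3, 4); col[match(b, DNA_BASES)] <- 231; col
  }
  counts <- cbind(c(40, 20, 20, 160),
                  vapply(c("C", "A", "C", "G", "T", "G"), core, numeric(4)),
                  c(160, 20, 20, 40))
  pfm(counts, name = "EBOX_SYNTH synthetic E-box")
}

#' Synthetic placeholder for a GC-rich (ASH2L-like) motif
#'
#' Clearly non-canonical stand-in with a GCGGCG-type consensus: the
#' published ASH2L matrix is not redistributed here. Use [read_jaspar()] to
#' supply a real matrix instead.
#'
#' @return A `pfm`.
#' @export
ash2l_like_pfm <- function() {
  col <- function(b, major = 150, minor = 30) {
    v <- rep(minor, 4); v[match(b, DNA_BASES)] <- major; v
  }
  counts <- vapply(c("G", "C", "G", "G", "C", "G"), col, numeric(4))
  pfm(counts, name = "ASH2L_LIKE_SYNTH synthetic placeholder")
}

# Largest-remainder allocation of n items to proportions (deterministic).
alloc_exact <- function(n, probs) {
  base <- floor(n * probs)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- n * probs - base
    top <- order(-frac, seq_along(probs))[seq_len(rem)]
    base[top] <- base[top] + 1
  }
  stats::setNames(as.integer(base), names(probs))
}

#' Configuration for the synthetic-data generator
#'
#' Defaults define the package's reference study conditions: a 2 x 1 Mb
#' genome carrying 500 non-overlapping 600 bp regulatory regions spaced 4 kb
#' apart with planted state labels, 400 genes, two TF peak groups whose
#' state-placement probabilities emulate genome-wide MYC/WDR5 marginals,
#' POL II occupancy led by 86% at active promoters, and read rates with
#' active promoters 10-fold above poised ones. All noise knobs are zero:
#' mark peaks coincide exactly with their regions, so recovery is exact.
#'
#' @param seed Master seed for every random draw.
#' @param chrom_lengths Named chromosome lengths (bp).
#' @param n_regions Number of planted regulatory regions.
#' @param region_width Region width (bp).
#' @param region_spacing Center-to-center region spacing (bp); must leave
#'   enhancers farther than the classification margin from promoters.
#' @param state_proportions Named proportions over [STATE_LABELS]; sum to 1.
#' @param n_genes Number of TSSs; every promoter-state region receives one,
#'   the rest are placed inside non-enhancer regions.
#' @param tf_groups Named list; each entry a list with `n_peaks`,
#'   `placement` (named per-state probabilities) and `motif_rate` (fraction
#'   of the group's peaks that get a planted motif at the summit).
#' @param tf_peak_width TF peak width (bp).
#' @param pfm Motif to plant (a `pfm`; default [ebox_pfm()]).
#' @param plant_mode `"consensus"` (deterministic word) or `"sample"` (drawn
#'   from the PFM column frequencies).
#' @param polii_rates Named per-state probabilities that a region gets a
#'   POL II peak.
#' @param read_rates Named per-state read rates (reads per bp).
#' @param read_length RNA read length (bp).
#' @param background Genome base composition (A, C, G, T).
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(
    seed = 1,
    chrom_lengths = c(chr1 = 1e6, chr2 = 1e6),
    n_regions = 500,
    region_width = 600,
    region_spacing = 4000,
    state_proportions = c(active_promoter = 0.24, active_enhancer = 0.16,
                          poised_promoter = 0.10, poised_enhancer = 0.12,
                          closed = 0.14, other = 0.24),
    n_genes = 400,
    tf_groups = list(
      MYC = list(n_peaks = 200,
                 placement = c(active_promoter = 0.30, active_enhancer = 0.26,
                               poised_promoter = 0.06, poised_enhancer = 0.08,
                               closed = 0.10, other = 0.20),
                 motif_rate = 0.6),
      WDR5 = list(n_peaks = 200,
                  placement = c(active_promoter = 0.11, active_enhancer = 0.03,
                                poised_promoter = 0.08, poised_enhancer = 0.13,
                                closed = 0.15, other = 0.50),
                  motif_rate = 0.3)),
    tf_peak_width = 250,
    pfm = ebox_pfm(),
    plant_mode = c("consensus", "sample"),
    polii_rates = c(active_promoter = 0.86, active_enhancer = 0.16,
                    poised_promoter = 0.06, poised_enhancer = 0.03,
                    closed = 0.001, other = 0.05),
    read_rates = c(active_promoter = 0.2, active_enhancer = 0.05,
                   poised_promoter = 0.02, poised_enhancer = 0.01,
                   closed = 0.002, other = 0.01),
    read_length = 36,
    background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  plant_mode <- match.arg(plant_mode)
  cfg <- list(seed = seed, chrom_lengths = chrom_lengths,
              n_regions = n_regions, region_width = region_width,
              region_spacing = region_spacing,
              state_proportions = state_proportions, n_genes = n_genes,
              tf_groups = tf_groups, tf_peak_width = tf_peak_width,
              pfm = pfm, plant_mode = plant_mode,
              polii_rates = polii_rates, read_rates = read_rates,
              read_length = read_length, background = background)
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  named_over_states <- function(x, what) {
    if (!setequal(names(x), STATE_LABELS))
      stop(what, " must be named over all six state labels")
    x[STATE_LABELS]
  }
  sp <- named_over_states(cfg$state_proportions, "state_proportions")
  if (abs(sum(sp) - 1) > 1e-9) stop("state_proportions must sum to 1")
  if (any(sp < 0)) stop("state_proportions must be >= 0")
  named_over_states(cfg$polii_rates, "polii_rates")
  named_over_states(cfg$read_rates, "read_rates")
  if (any(cfg$polii_rates < 0 | cfg$polii_rates > 1))
    stop("polii_rates must be probabilities")
  if (any(cfg$read_rates < 0)) stop("read_rates must be >= 0")
  for (g in names(cfg$tf_groups)) {
    grp <- cfg$tf_groups[[g]]
    pl <- named_over_states(grp$placement, paste0("placement[", g, "]"))
    if (abs(sum(pl) - 1) > 1e-9)
      stop("placement probabilities for ", g, " must sum to 1")
    if (grp$motif_rate < 0 || grp$motif_rate > 1)
      stop("motif_rate for ", g, " must be in [0, 1]")
  }
  if (cfg$region_width + 400 > cfg$region_spacing)
    stop("region_spacing too small for the region width")
  invisible(cfg)
}

#' Plant a motif word into a sequence
#'
#' Overwrites W bases starting at 0-based `position` with either the PFM
#' consensus word or a word sampled from the PFM column frequencies.
#'
#' @param seq Sequence string.
#' @param x A `pfm`.
#' @param position 0-based start of the planted word.
#' @param mode `"consensus"` or `"sample"`.
#' @return The modified sequence string.
#' @export
plant_motif <- function(seq, x, position,
                        mode = c("consensus", "sample")) {
  mode <- match.arg(mode)
  w <- pwm_width(x)
  if (position < 0 || position + w > nchar(seq))
    stop("planting position out of range")
  word <- motif_word(x, mode)
  paste0(substring(seq, 1, position), word,
         substring(seq, position + w + 1, nchar(seq)))
}

motif_word <- function(x, mode) {
  counts <- x$counts
  bases <- if (mode == "consensus") {
    DNA_BASES[apply(counts, 2, which.max)]
  } else {
    apply(counts, 2, function(col)
      sample(DNA_BASES, 1, prob = col / sum(col)))
  }
  paste(bases, collapse = "")
}

#' Generate a synthetic dataset with planted truth
#'
#' Writes a complete on-disk dataset (genome FASTA, chrom.sizes, TSS BED,
#' per-mark narrowPeak files consistent with each region's planted label
#' under the classification rules, TF narrowPeak files with summits centered
#' on planted motif words, POL II peaks at per-state rates, an RNA reads BED
#' with per-region Poisson counts, a JASPAR motif file, truth TSVs and a
#' manifest) and returns it together with in-memory objects. Byte-identical
#' across runs with the same config.
#'
#' @param config A [synthetic_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with `paths`, `truth` (region and TF-peak
#'   data.frames), `config`, and in-memory `layout`, `regions`, `marks`,
#'   `tss`, `tf_peaks`, `reads`, `genome`.
#' @export
generate_dataset <- function(config, dir) {
  validate_synthetic_config(config)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  layout <- genome_layout(config$chrom_lengths)
  rw <- config$region_width
  half <- rw %/% 2L

  ## region slots: centers every region_spacing bp, chromosome by chromosome
  slots <- do.call(rbind, lapply(seqlevels(layout), function(chr) {
    len <- seqlengths(layout)[[chr]]
    centers <- seq(config$region_spacing %/% 2L, len - half,
                   by = config$region_spacing)
    centers <- centers[centers - half >= 0]
    data.frame(chrom = chr, center0 = centers)
  }))
  if (nrow(slots) < config$n_regions)
    stop("infeasible packing: only ", nrow(slots), " region slots for ",
         config$n_regions, " regions")
  slots <- slots[seq_len(config$n_regions), ]

  ## planted labels: exact allocation, then shuffled
  counts <- alloc_exact(config$n_regions,
                        config$state_proportions[STATE_LABELS])
  labels <- sample(rep(STATE_LABELS, counts))
  regions <- GRanges(slots$chrom,
                     IRanges(slots$center0 - half + 1L,
                             slots$center0 + (rw - half)),
                     seqinfo = layout)
  mcols(regions)$region_id <- seq_along(regions)
  mcols(regions)$label <- labels
  center1 <- slots$center0 + 1L

  ## TSSs: one per promoter-state region, the rest inside non-enhancer
  ## regions (a core-promoter window there does not change any label)
  prom_idx <- which(labels %in% c("active_promoter", "poised_promoter"))
  if (config$n_genes < length(prom_idx))
    stop("n_genes must cover every promoter-state region (need >= ",
         length(prom_idx), ")")
  n_decoy <- config$n_genes - length(prom_idx)
  decoy_pool <- c(which(labels %in% c("closed", "other")), prom_idx)
  decoy_idx <- rep(decoy_pool, length.out = n_decoy)
  tss_region <- c(prom_idx, decoy_idx)
  tss_off0 <- c(rep(300L, length(prom_idx)), rep(150L, n_decoy))
  tss0 <- (start(regions)[tss_region] - 1L) + tss_off0
  tss_strand <- sample(c("+", "-"), length(tss_region), replace = TRUE)
  tss <- GRanges(seqnames(regions)[tss_region],
                 IRanges(tss0 + 1L, tss0 + 1L),
                 strand = tss_strand, seqinfo = layout)
  mcols(tss)$name <- sprintf("gene_%03d", seq_along(tss))

  ## histone-mark peaks coincide with their regions (noise-free)
  mark_of <- list(H3K4me3 = c("active_promoter", "poised_promoter"),
                  H3K4me1 = c("active_enhancer", "poised_enhancer"),
                  H3K27ac = c("active_promoter", "active_enhancer"),
                  H3K27me3 = c("poised_promoter", "closed"))
  mark_peaks <- lapply(mark_of, function(states) {
    sel <- regions[labels %in% states]
    mcols(sel) <- NULL
    mcols(sel)$summit <- center1[labels %in% states]
    sel
  })

  ## genome: i.i.d. bases, as character vectors so motifs can be planted
  genome_chars <- lapply(seqlengths(layout), function(len)
    sample(DNA_BASES, len, replace = TRUE, prob = config$background))

  ## TF peaks: exact per-state allocation, summit at the region center
  w_motif <- pwm_width(config$pfm)
  tfw <- config$tf_peak_width
  truth_tf <- list()
  tf_peaks <- list()
  for (g in names(config$tf_groups)) {
    grp <- config$tf_groups[[g]]
    alloc <- alloc_exact(grp$n_peaks, grp$placement[STATE_LABELS])
    picked <- integer(0)
    for (s in STATE_LABELS) {
      avail <- which(labels == s)
      if (alloc[[s]] > length(avail))
        stop("infeasible placement: group ", g, " needs ", alloc[[s]],
             " regions of state ", s, " but only ", length(avail), " exist")
      picked <- c(picked, avail[sample.int(length(avail), alloc[[s]])])
    }
    summit0 <- (center1 - 1L)[picked]
    pk <- GRanges(seqnames(regions)[picked],
                  IRanges(summit0 - (tfw %/% 2L) + 1L,
                          summit0 + (tfw - tfw %/% 2L)),
                  seqinfo = layout)
    mcols(pk)$name <- sprintf("%s_peak_%03d", g, seq_along(pk))
    mcols(pk)$score <- rep(0, length(pk))
    mcols(pk)$summit <- summit0 + 1L
    n_plant <- round(grp$motif_rate * grp$n_peaks)
    planted <- rep(FALSE, length(pk))
    planted[sample(length(pk), n_plant)] <- TRUE
    words <- rep(NA_character_, length(pk))
    pos0 <- ifelse(planted, summit0 - (w_motif %/% 2L), NA_integer_)
    for (i in which(planted)) {
      chr <- as.character(seqnames(pk))[i]
      word <- motif_word(config$pfm, config$plant_mode)
      genome_chars[[chr]][(pos0[i] + 1L):(pos0[i] + w_motif)] <-
        strsplit(word, "")[[1]]
      words[i] <- word
    }
    tf_peaks[[g]] <- pk
    truth_tf[[g]] <- data.frame(
      group = g, name = mcols(pk)$name,
      chrom = as.character(seqnames(pk)),
      start = start(pk) - 1L, end = end(pk), summit = summit0,
      region_id = picked, label = labels[picked],
      motif_planted = planted, motif_pos = pos0, motif_word = words)
  }
  truth_tf <- do.call(rbind, truth_tf)
  rownames(truth_tf) <- NULL

  ## POL II peaks: Bernoulli per region at the per-state rate
  polii_hit <- rbinom(length(regions), 1,
                      config$polii_rates[labels]) == 1
  pol2 <- regions[polii_hit]
  mcols(pol2) <- NULL
  mcols(pol2)$summit <- center1[polii_hit]

  ## RNA reads: Poisson per region at the per-state rate
  read_counts <- rpois(length(regions),
                       config$read_rates[labels] * width(regions))
  ridx <- rep(seq_along(regions), read_counts)
  if (length(ridx)) {
    lo <- start(regions)[ridx]
    hi <- pmax(end(regions)[ridx] - config$read_length + 1L, lo)
    s <- lo + floor(runif(length(ridx)) * (hi - lo + 1L))
    reads <- GRanges(seqnames(regions)[ridx],
                     IRanges(s, pmin(s + config$read_length - 1L,
                                     end(regions)[ridx])),
                     seqinfo = layout)
  } else {
    reads <- GRanges(seqinfo = layout)
  }

  ## consistency check before anything is written
  core_prom <- upstream_window(tss, 200)
  marks <- do.call(mark_collection, c(mark_peaks, list(POL2 = pol2)))
  recovered <- classify_loci(regions, marks, core_prom)
  if (!all(as.character(recovered) == labels))
    stop("internal error: planted labels not recovered from planted marks")

  ## write everything
  paths <- list(
    genome_fasta = file.path(dir, "genome.fa"),
    chrom_sizes = file.path(dir, "genome.chrom.sizes"),
    tss_bed = file.path(dir, "tss.bed"),
    reads_bed = file.path(dir, "reads.bed"),
    motif_jaspar = file.path(dir, "motif.jaspar"),
    truth_regions = file.path(dir, "truth_regions.tsv"),
    truth_tf_peaks = file.path(dir, "truth_tf_peaks.tsv"),
    manifest = file.path(dir, "manifest.json"))
  for (m in names(mark_peaks))
    paths[[m]] <- file.path(dir, paste0(m, ".narrowPeak"))
  paths$POL2 <- file.path(dir, "POL2.narrowPeak")
  for (g in names(tf_peaks))
    paths[[g]] <- file.path(dir, paste0(g, ".narrowPeak"))

  genome <- DNAStringSet(vapply(genome_chars, paste, "", collapse = ""))
  names(genome) <- seqlevels(layout)
  writeXStringSet(genome, paths$genome_fasta)
  write_chrom_sizes(layout, paths$chrom_sizes)
  write_bed(tss, paths$tss_bed)
  for (m in names(mark_peaks)) write_narrowpeak(mark_peaks[[m]], paths[[m]])
  write_narrowpeak(pol2, paths$POL2)
  for (g in names(tf_peaks)) write_narrowpeak(tf_peaks[[g]], paths[[g]])
  write_bed(reads, paths$reads_bed)
  write_jaspar(config$pfm, paths$motif_jaspar)

  truth_regions <- data.frame(
    region_id = mcols(regions)$region_id,
    chrom = as.character(seqnames(regions)),
    start = start(regions) - 1L, end = end(regions),
    label = labels, polii = polii_hit,
    read_rate = unname(config$read_rates[labels]),
    read_count = read_counts)
  write.table(truth_regions, paths$truth_regions, sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(truth_tf, paths$truth_tf_peaks, sep = "\t",
              quote = FALSE, row.names = FALSE)

  manifest <- list(
    generator = "peakstates::generate_dataset",
    seed = config$seed,
    n_regions = config$n_regions,
    n_genes = config$n_genes,
    state_counts = as.list(counts),
    files = lapply(paths[names(paths) != "manifest"], basename))
  write_json(manifest, paths$manifest, auto_unbox = TRUE, pretty = TRUE,
             digits = NA)

  invisible(list(paths = paths,
                 truth = list(regions = truth_regions, tf_peaks = truth_tf),
                 config = config, layout = layout, regions = regions,
                 marks = marks, tss = tss, core_promoters = core_prom,
                 tf_peaks = tf_peaks, reads = reads, genome = genome))
}

#' Verify a written dataset against its truth files
#'
#' Re-reads the emitted files, re-classifies every truth region from the
#' emitted mark peaks and TSSs, checks TF-peak coordinates against the truth
#' table, and checks that every planted motif word is present in the genome
#' at its recorded position.
#'
#' @param paths The `paths` element returned by [generate_dataset()] (or a
#'   directory containing a generated dataset with default file names).
#' @return TRUE invisibly; stops with a message on any inconsistency.
#' @export
verify_truth <- function(paths) {
  if (is.character(paths) && length(paths) == 1 && dir.exists(paths)) {
    dir <- paths
    paths <- list(
      genome_fasta = file.path(dir, "genome.fa"),
      chrom_sizes = file.path(dir, "genome.chrom.sizes"),
      tss_bed = file.path(dir, "tss.bed"),
      truth_regions = file.path(dir, "truth_regions.tsv"),
      truth_tf_peaks = file.path(dir, "truth_tf_peaks.tsv"))
    for (m in c("H3K4me3", "H3K4me1", "H3K27ac", "H3K27me3", "POL2"))
      paths[[m]] <- file.path(dir, paste0(m, ".narrowPeak"))
  }
  layout <- read_chrom_sizes(paths$chrom_sizes)
  marks <- mark_collection(
    H3K4me3 = read_narrowpeak(paths$H3K4me3, layout),
    H3K4me1 = read_narrowpeak(paths$H3K4me1, layout),
    H3K27ac = read_narrowpeak(paths$H3K27ac, layout),
    H3K27me3 = read_narrowpeak(paths$H3K27me3, layout),
    POL2 = read_narrowpeak(paths$POL2, layout))
  tss <- read_bed(paths$tss_bed, layout)
  core_prom <- upstream_window(tss, 200)
  tr <- read.table(paths$truth_regions, sep = "\t", header = TRUE)
  regions <- GRanges(tr$chrom, IRanges(tr$start + 1L, tr$end),
                     seqinfo = layout)
  lab <- classify_loci(regions, marks, core_prom)
  if (!all(as.character(lab) == tr$label))
    stop("truth inconsistency: ", sum(lab != tr$label),
         " region labels not recovered from the emitted files")
  tt <- read.table(paths$truth_tf_peaks, sep = "\t", header = TRUE)
  genome <- read_genome_fasta(paths$genome_fasta)
  chars <- stats::setNames(toupper(as.character(genome)), names(genome))
  planted <- tt[tt$motif_planted, ]
  if (nrow(planted)) {
    seen <- substring(chars[planted$chrom], planted$motif_pos + 1L,
                      planted$motif_pos + nchar(planted$motif_word))
    if (!all(seen == planted$motif_word))
      stop("truth inconsistency: planted motif word absent from genome")
  }
  invisible(TRUE)
}
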