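# End-to-end orchestration: config validation, the four analysis stages
# (state assignment, POL II occupancy, motif enrichment, expression linkage)
# and a consolidated on-disk report with a run log.

run_config_defaults <- list(
  core_promoter_width = 200,
  summit_flank = 125,
  expression_flank = 1000,
  alpha = 1e-4,
  enhancer_margin = 2000,
  pseudocount = 0.8,
  bin_width = 0.01,
  log_offset = 0.1,
  expression_reference = "WDR5",
  seed = 1
)

#' Validate and normalize a pipeline run configuration
#'
#' Fills defaults (core-promoter width 200 bp, summit flank 125 bp,
#' expression flank 1000 bp, per-position false-positive rate 1e-4,
#' enhancer margin 2000 bp, pseudocount 0.8, score bin width 0.01 bits) and
#' collects every problem as `key: reason`.
#'
#' @param config A named list, or the path of a YAML file holding one.
#'   Required keys: `genome_fasta`, `chrom_sizes`, `tss_bed`, `marks` (named
#'   list of narrowPeak/BED paths for H3K4me3, H3K4me1, H3K27ac, H3K27me3),
#'   `tf_peaks` (named list of narrowPeak paths), `motif_jaspar`. Optional:
#'   `pol2`, `reads_bed`, parameter overrides.
#' @return The normalized config; stops listing all errors if any.
#' @export
validate_run_config <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  errors <- character(0)
  adderr <- function(key, why) errors[[length(errors) + 1]] <<-
    paste0(key, ": ", why)
  for (p in names(run_config_defaults))
    if (is.null(config[[p]])) config[[p]] <- run_config_defaults[[p]]
  num_ok <- function(key, lo, hi, open = FALSE) {
    v <- config[[key]]
    if (!is.numeric(v) || length(v) != 1 ||
        (open && (v <= lo || v >= hi)) || (!open && (v < lo || v > hi)))
      adderr(key, sprintf("must be a number in %s%g, %g%s",
                          if (open) "(" else "[", lo, hi,
                          if (open) ")" else "]"))
  }
  num_ok("alpha", 0, 1, open = TRUE)
  num_ok("core_promoter_width", 1, Inf)
  num_ok("summit_flank", 0, Inf)
  num_ok("expression_flank", 0, Inf)
  num_ok("enhancer_margin", 0, Inf)
  num_ok("pseudocount", 0, Inf)
  if (!is.numeric(config$bin_width) || config$bin_width <= 0)
    adderr("bin_width", "must be > 0")
  for (key in c("genome_fasta", "chrom_sizes", "tss_bed", "motif_jaspar")) {
    if (is.null(config[[key]])) adderr(key, "missing")
    else if (!file.exists(config[[key]])) adderr(key, "file not found")
  }
  mark_names <- c("H3K4me3", "H3K4me1", "H3K27ac", "H3K27me3")
  if (is.null(config$marks)) {
    adderr("marks", "missing")
  } else {
    for (m in mark_names) {
      if (is.null(config$marks[[m]]))
        adderr(paste0("marks$", m), "missing mark file")
      else if (!file.exists(config$marks[[m]]))
        adderr(paste0("marks$", m), "file not found")
    }
  }
  if (is.null(config$tf_peaks) || !length(names(config$tf_peaks)))
    adderr("tf_peaks", "need at least one named TF peak file")
  else for (g in names(config$tf_peaks)) {
    if (is.null(config$tf_peaks[[g]]) ||
        !is.character(config$tf_peaks[[g]]))
      adderr(paste0("tf_peaks$", g), "missing path")
    else if (!file.exists(config$tf_peaks[[g]]))
      adderr(paste0("tf_peaks$", g), "file not found")
  }
  for (key in c("pol2", "reads_bed"))
    if (!is.null(config[[key]]) && !file.exists(config[[key]]))
      adderr(key, "file not found")
  if (length(errors))
    stop("invalid run config:\n  ", paste(errors, collapse = "\n  "))
  config
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full pipeline
#'
#' Loads all inputs, derives joint regions for the first two TF groups,
#' relates every group to the six chromatin states, measures POL II
#' occupancy of the feature regions, fixes the motif bit-score threshold
#' from the exact null distribution at the configured false-positive rate,
#' tests motif enrichment of summit-extended peak windows against matched
#' random background regions, and compares reads-per-kbp of
#' promoter-proximal peak windows between groups. Tables are written as TSV
#' together with a manifest and a plain-text log; the run is deterministic
#' under the configured seed.
#'
#' @param config See [validate_run_config()].
#' @param out_dir Output directory.
#' @return Invisibly, a list of the report tables
#'   (`feature_assignment`, `polii_occupancy`, `motif_enrichment`,
#'   `expression_summary`, `expression_comparisons`, plus `threshold_bits`
#'   and `paths`).
#' @export
run_pipeline <- function(config, out_dir) {
  config <- validate_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run_log.txt")
  logf <- function(fmt, ...) cat(sprintf(paste0(fmt, "\n"), ...),
                                 file = log_path, append = TRUE)
  cat(sprintf("peakstates %s\nseed: %d\n",
              as.character(utils::packageVersion("peakstates")),
              as.integer(config$seed)),
      file = log_path)
  for (p in names(run_config_defaults))
    logf("param %s = %s", p, format(config[[p]]))

  stage <- "load inputs"
  tables <- tryCatch({
    layout <- read_chrom_sizes(config$chrom_sizes)
    genome <- read_genome_fasta(config$genome_fasta)
    tss <- read_bed(config$tss_bed, layout)
    marks_in <- lapply(config$marks, read_narrowpeak, layout = layout)
    pol2 <- if (!is.null(config$pol2))
      read_narrowpeak(config$pol2, layout) else NULL
    marks <- do.call(mark_collection, c(marks_in, list(POL2 = pol2)))
    groups <- lapply(config$tf_peaks, read_narrowpeak, layout = layout)
    reads <- if (!is.null(config$reads_bed))
      read_bed(config$reads_bed, layout) else NULL
    motif <- read_jaspar(config$motif_jaspar)
    logf("loaded %d TSSs, %s TF groups (%s)", length(tss),
         length(groups), paste(names(groups), collapse = ", "))

    stage <- "chromatin-state assignment"
    core_prom <- upstream_window(tss, config$core_promoter_width)
    if (length(groups) >= 2) {
      jn <- paste(names(groups)[1:2], collapse = "+")
      groups[[jn]] <- joint_regions(groups[[1]], groups[[2]])
      logf("joint regions (%s): %d", jn, length(groups[[jn]]))
    }
    assignment <- assign_peaks(groups, marks, core_prom,
                               margin = config$enhancer_margin)

    stage <- "POL II occupancy"
    occupancy <- if (!is.null(pol2)) {
      feats <- feature_regions(marks, core_prom,
                               margin = config$enhancer_margin)
      polii_occupancy(feats, pol2)
    } else NULL

    stage <- "motif enrichment"
    pwm <- pfm_to_pwm(motif, background = genome_base_freq(genome),
                      pseudocount = config$pseudocount)
    dist <- exact_null_distribution(pwm, eps = config$bin_width)
    threshold <- threshold_for_fpr(dist, alpha = config$alpha)
    logf("motif %s: threshold %.4f bits at alpha %g",
         attr(pwm, "name"), as.numeric(threshold), config$alpha)
    all_tf <- reduce(do.call(c, unname(lapply(groups, granges))),
                     ignore.strand = TRUE)
    enrich <- do.call(rbind, lapply(names(groups), function(g) {
      win <- extend_about_summit(groups[[g]], config$summit_flank)
      bg <- sample_background_regions(
        length(win), as.integer(2 * config$summit_flank + 1), layout,
        excluded = all_tf, seed = config$seed + 1)
      r <- enrichment_test(fetch_sequence(win, genome),
                           fetch_sequence(bg, genome), pwm, threshold)
      data.frame(group = g, n = r$n_peaks, hits = r$peak_hits,
                 proportion = r$peak_prop, bg_n = r$n_bg,
                 bg_hits = r$bg_hits, bg_proportion = r$bg_prop,
                 fisher_p = r$fisher_p, z = r$z, z_p = r$z_p,
                 threshold_bits = r$threshold_bits)
    }))

    stage <- "expression linkage"
    expression_summary <- NULL
    comparisons <- NULL
    expr <- NULL
    if (!is.null(reads)) {
      expr <- lapply(names(groups), function(g) {
        prox <- promoter_proximal(groups[[g]], core_prom)
        if (!length(prox)) {
          warning("group '", g, "' has no promoter-proximal peaks")
          return(data.frame())
        }
        win <- extend_about_summit(prox, config$expression_flank)
        cbind(group = g, expression_table(win, reads,
                                          offset = config$log_offset))
      })
      names(expr) <- names(groups)
      expression_summary <- do.call(rbind, lapply(names(expr), function(g) {
        e <- expr[[g]]
        data.frame(group = g, n = nrow(e),
                   mean_rpk = if (nrow(e)) mean(e$rpk) else NA_real_,
                   median_rpk = if (nrow(e)) stats::median(e$rpk) else NA_real_,
                   median_log_rpk = if (nrow(e))
                     stats::median(e$log_rpk) else NA_real_)
      }))
      ref <- config$expression_reference
      if (!ref %in% names(expr)) ref <- names(expr)[1]
      others <- setdiff(names(expr), ref)
      comparisons <- do.call(rbind, lapply(others, function(g) {
        if (nrow(expr[[g]]) < 2 || nrow(expr[[ref]]) < 2) return(NULL)
        cmp <- compare_expression(expr[[g]]$rpk, expr[[ref]]$rpk,
                                  offset = config$log_offset)
        data.frame(group = g, reference = ref,
                   n = cmp$n_a, n_ref = cmp$n_b,
                   median = cmp$median_a, median_ref = cmp$median_b,
                   mean_ratio = cmp$mean_ratio,
                   rank_biserial = cmp$rank_biserial,
                   wilcox_p = cmp$wilcox_p, welch_p = cmp$welch_p)
      }))
    }

    list(feature_assignment = assignment, polii_occupancy = occupancy,
         motif_enrichment = enrich, expression_summary = expression_summary,
         expression_comparisons = comparisons, expression_windows = expr,
         threshold_bits = as.numeric(threshold))
  }, error = function(e) {
    logf("FAILED at stage '%s': %s", stage, conditionMessage(e))
    stop("pipeline failed at stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  })

  stage <- "write report"
  paths <- list(feature_assignment = file.path(out_dir,
                                               "feature_assignment.tsv"),
                motif_enrichment = file.path(out_dir,
                                             "motif_enrichment.tsv"))
  write_tsv(tables$feature_assignment, paths$feature_assignment)
  write_tsv(tables$motif_enrichment, paths$motif_enrichment)
  if (!is.null(tables$polii_occupancy)) {
    paths$polii_occupancy <- file.path(out_dir, "polii_occupancy.tsv")
    write_tsv(tables$polii_occupancy, paths$polii_occupancy)
  }
  if (!is.null(tables$expression_summary)) {
    paths$expression_summary <- file.path(out_dir, "expression_summary.tsv")
    write_tsv(tables$expression_summary, paths$expression_summary)
    nonempty <- Filter(nrow, tables$expression_windows)
    if (length(nonempty)) {
      paths$expression_windows <- file.path(out_dir,
                                            "expression_windows.tsv")
      write_tsv(do.call(rbind, nonempty), paths$expression_windows)
    }
  }
  if (!is.null(tables$expression_comparisons) &&
      nrow(tables$expression_comparisons)) {
    paths$expression_comparisons <-
      file.path(out_dir, "expression_comparisons.tsv")
    write_tsv(tables$expression_comparisons, paths$expression_comparisons)
  }
  manifest <- list(tables = lapply(paths, basename),
                   seed = as.integer(config$seed),
                   threshold_bits = tables$threshold_bits)
  write_json(manifest, file.path(out_dir, "manifest.json"),
             auto_unbox = TRUE, pretty = TRUE, digits = NA)
  logf("wrote %d tables to %s", length(paths), out_dir)
  tables$paths <- paths
  invisible(tables)
}

#' Base composition of a genome
#' @param genome DNAStringSet.
#' @return Named A/C/G/T frequency vector (N and ambiguity codes ignored).
#' @export
genome_base_freq <- function(genome) {
  counts <- colSums(Biostrings::alphabetFrequency(genome)[, DNA_BASES,
                                                          drop = FALSE])
  counts / sum(counts)
}
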