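test_that("JASPAR PFM text round-trips and validates", {
  path <- withr::local_tempfile(fileext = ".jaspar")
  writeLines(c(">TOY toy",
               "A [ 4 0 ]", "C [ 0 4 ]", "G [ 0 0 ]", "T [ 0 0 ]"), path)
  x <- read_jaspar(path)
  expect_equal(pwm_width(x), 2)
  expect_equal(unname(x$counts["A", 1]), 4)
  expect_equal(unname(x$counts["C", 2]), 4)

  writeLines(c(">TOY toy", "A [ 4 0 ]", "C [ 0 4 ]", "G [ 0 0 ]"), path)
  expect_error(read_jaspar(path), "A/C/G/T")
  writeLines(c(">TOY toy",
               "A [ 4 0 ]", "C [ 0 4 ]", "G [ 0 0 ]", "T [ 0 ]"), path)
  expect_error(read_jaspar(path), "unequal")

  path2 <- withr::local_tempfile(fileext = ".jaspar")
  write_jaspar(ebox_pfm(), path2)
  back <- read_jaspar(path2)
  expect_equal(back$counts, ebox_pfm()$counts)
  expect_equal(back$name, ebox_pfm()$name)
})

test_that("log-odds entries follow the PWM definition", {
  uni <- rep(0.25, 4)
  m1 <- pfm_to_pwm(pfm(matrix(c(4, 0, 0, 0), 4)), uni, pseudocount = 0)
  expect_equal(unname(unclass(m1)["A", 1]), 2.0)  # log2(1 / 0.25)
  expect_equal(unname(unclass(m1)["C", 1]), -Inf)

  m2 <- pfm_to_pwm(pfm(matrix(1, 4, 1)), uni, pseudocount = 0)
  expect_equal(as.numeric(unclass(m2)), rep(0, 4))

  # (3,1,0,0) with total pseudocount 1 spread by a uniform background:
  # A entry = log2(((3 + 0.25) / (4 + 1)) / 0.25) = log2(2.6)
  m3 <- pfm_to_pwm(pfm(matrix(c(3, 1, 0, 0), 4)), uni, pseudocount = 1)
  expect_equal(unname(unclass(m3)["A", 1]), log2(2.6), tolerance = 1e-12)

  expect_error(pfm_to_pwm(pfm(matrix(1, 4, 1)), c(0.5, 0.5, 0, 0)),
               "positive")
})

test_that("window scoring sums per-position bits with N as -Inf", {
  pwm <- certain_pwm3()
  expect_equal(score_window(pwm, "CAC"), 6.0)
  expect_equal(score_window(pwm, "CAA"), -Inf)
  expect_equal(score_window(pwm, "CNC"), -Inf)
  expect_error(score_window(pwm, "CACG"), "width")
})

test_that("both-strand scan finds planted sites with deterministic tie-breaks", {
  ebox <- certain_ebox6()
  res <- scan_region(ebox, "TTCACGTGTT")
  expect_equal(res$best$offset, 2)
  expect_equal(res$best$score, 12)
  # CACGTG is its own reverse complement: the + strand wins the tie
  expect_equal(res$best$strand, "+")
  hits <- scan_region(ebox, "TTCACGTGTT", threshold = 12)$hits
  expect_equal(nrow(hits), 2)
  expect_setequal(hits$strand, c("+", "-"))
  expect_true(all(hits$offset == 2))
})

test_that("scan agrees with per-window rescoring on both strands", {
  set.seed(5)
  pwm <- pfm_to_pwm(random_pfm(5), random_background())
  w <- 5
  for (i in 1:50) {
    seq <- random_seq(40)
    got <- scan_region(pwm, seq, threshold = -Inf)$hits
    # oracle: rescore every window explicitly on both strands
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(seq)))
    exp <- do.call(rbind, lapply(0:(40 - w), function(off) {
      fwd <- score_window(pwm, substring(seq, off + 1, off + w))
      rev_off <- 40 - w - off
      rev <- score_window(pwm, substring(rc, rev_off + 1, rev_off + w))
      rbind(data.frame(offset = off, strand = "+", score = fwd),
            data.frame(offset = off, strand = "-", score = rev))
    }))
    got <- got[order(got$offset, got$strand), ]
    exp <- exp[order(exp$offset, exp$strand), ]
    expect_equal(got$score, exp$score, tolerance = 1e-12)
  }
})

test_that("scanning a reverse-complemented region mirrors the hit set", {
  set.seed(6)
  pwm <- pfm_to_pwm(random_pfm(6), random_background())
  for (i in 1:20) {
    seq <- random_seq(60)
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(seq)))
    h1 <- scan_region(pwm, seq, threshold = -Inf)$hits
    h2 <- scan_region(pwm, rc, threshold = -Inf)$hits
    m1 <- h1[order(h1$offset, h1$strand), ]
    # mirroring: offset o on + of rc corresponds to offset L-W-o on - of seq
    h2$offset <- 60 - 6 - h2$offset
    h2$strand <- ifelse(h2$strand == "+", "-", "+")
    m2 <- h2[order(h2$offset, h2$strand), ]
    expect_equal(m1$score, m2$score, tolerance = 1e-12)
  }
})

test_that("exact null distribution matches the enumeration oracle", {
  # certain width-3 PWM: only the consensus word scores finitely
  d <- exact_null_distribution(certain_pwm3(), eps = 0.01)
  expect_equal(d$score, 6.0)
  expect_equal(d$prob, 1 / 64)
  expect_equal(d$p_impossible, 63 / 64)
  expect_equal(score_tail(d, 6.0), 1 / 64)

  set.seed(8)
  for (w in 3:6) {
    pwm <- pfm_to_pwm(random_pfm(w), random_background(), pseudocount = 0.8)
    d <- exact_null_distribution(pwm, eps = 0.01)
    expect_equal(sum(d$prob) + d$p_impossible, 1, tolerance = 1e-12)
    expect_true(all(diff(d$tail) <= 1e-15))
    oracle <- enum_null_grid(pwm, 0.01)
    expect_equal(d$score, oracle$score, tolerance = 1e-9)
    expect_equal(d$prob, oracle$prob, tolerance = 1e-12)
  }
})

test_that("threshold selection controls the per-position tail", {
  d3 <- exact_null_distribution(certain_pwm3(), eps = 0.01)
  t1 <- threshold_for_fpr(d3, 0.02)        # tail(6) = 1/64 <= 0.02
  expect_equal(as.numeric(t1), 6.0)
  expect_false(attr(t1, "unattainable"))
  t2 <- threshold_for_fpr(d3, 1e-4)        # min word probability 1/64 > 1e-4
  expect_true(is.infinite(t2))
  expect_true(attr(t2, "unattainable"))
  t3 <- threshold_for_fpr(d3, 0.999)
  expect_equal(as.numeric(t3), min(d3$score))
  expect_error(threshold_for_fpr(d3, 2), "alpha")
})

test_that("background regions are reproducible, constrained and uniform", {
  layout <- genome_layout(c(chr1 = 2e6))
  a <- sample_background_regions(50, 250, layout, seed = 99)
  b <- sample_background_regions(50, 250, layout, seed = 99)
  expect_identical(granges(a), granges(b))

  # exclusion: whole chromosome except one 300 bp gap
  gap_start0 <- 1000000
  excluded <- gr0("chr1", c(0, gap_start0 + 300), c(gap_start0, 2e6),
                  layout = layout)
  g <- sample_background_regions(1, 250, layout, excluded, seed = 1)
  expect_gte(start(g) - 1L, gap_start0)
  expect_lte(end(g), gap_start0 + 300)
  everything <- gr0("chr1", 0, 2e6, layout = layout)
  expect_error(
    sample_background_regions(5, 250, layout, everything, seed = 1),
    "no room")

  # uniform starts: chi-square over 20 equal bins at the 1% level
  s <- sample_background_regions(1000, 250, layout, seed = 7)
  bins <- cut(start(s), breaks = seq(0, 2e6, length.out = 21))
  p <- stats::chisq.test(table(bins))$p.value
  expect_gt(p, 0.01)
})

test_that("one-sided Fisher p equals hypergeometric enumeration", {
  # 8/10 peaks vs 2/10 background
  p <- fisher_p_greater(8, 10, 2, 10)
  expect_equal(p, 2126 / 184756, tolerance = 1e-12)
  expect_equal(p, 0.01151, tolerance = 1e-3)
  expect_equal(p, fisher_enum(8, 10, 2, 10), tolerance = 1e-12)
  # identical proportions are never 'enriched'
  expect_gte(fisher_p_greater(5, 10, 5, 10), 0.5)
  # spot-check against stats::fisher.test on random tables
  set.seed(13)
  for (i in 1:50) {
    n1 <- sample.int(25, 1); n2 <- sample.int(25, 1)
    k1 <- sample.int(n1 + 1, 1) - 1; k2 <- sample.int(n2 + 1, 1) - 1
    ft <- stats::fisher.test(matrix(c(k1, n1 - k1, k2, n2 - k2), 2,
                                    byrow = TRUE),
                             alternative = "greater")$p.value
    expect_equal(fisher_p_greater(k1, n1, k2, n2), ft, tolerance = 1e-9)
  }
})

test_that("enrichment test counts window presence and guards degeneracy", {
  ebox <- certain_ebox6()
  d <- exact_null_distribution(ebox, eps = 0.01)
  thr <- threshold_for_fpr(d, 0.001)  # tail(12) = 4^-6 ~ 2.4e-4
  expect_equal(as.numeric(thr), 12)
  peak <- c(rep("TTCACGTGTT", 8), rep("TTTTTTTTTT", 2))
  bg <- c(rep("TTCACGTGTT", 2), rep("TTTTTTTTTT", 8))
  r <- enrichment_test(peak, bg, ebox, thr)
  expect_equal(r$peak_hits, 8)
  expect_equal(r$bg_hits, 2)
  expect_equal(r$fisher_p, fisher_enum(8, 10, 2, 10), tolerance = 1e-12)
  expect_gt(r$z, 0)
  expect_warning(enrichment_test(character(0), bg, ebox, thr), "empty")
  # unattainable sentinel: no hits anywhere
  expect_warning(r0 <- enrichment_test(peak, bg, ebox, Inf), "degenerate")
  expect_equal(r0$peak_hits + r0$bg_hits, 0)
})
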