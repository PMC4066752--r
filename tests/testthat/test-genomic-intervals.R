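# All expected coordinates in comments/tests are BED-style 0-based
# half-open unless they index a GRanges (1-based closed).

test_that("read_bed parses BED3/BED6 and converts coordinates", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t10\t20", "chr2\t0\t5\tg1\t0\t-"), path)
  gr <- read_bed(path)
  expect_equal(start(gr), c(11L, 1L))  # 0-based 10 and 0
  expect_equal(end(gr), c(20L, 5L))
  expect_equal(as.character(strand(gr)), c("*", "-"))
  expect_equal(mcols(gr)$name[2], "g1")
})

test_that("read_bed rejects malformed input naming the line", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t1\t2", "chr1\t20\t10"), path)
  expect_error(read_bed(path), "line 2")
  writeLines(c("chr1\t1"), path)
  expect_error(read_bed(path), "line 1")
  writeLines(c("chr1\tx\t10"), path)
  expect_error(read_bed(path), "line 1")
})

test_that("BED round-trips through write and re-read", {
  set.seed(42)
  gr <- random_intervals(50, toy_layout)
  strand(gr) <- sample(c("+", "-", "*"), 50, replace = TRUE)
  mcols(gr)$name <- sprintf("iv%02d", 1:50)
  path <- withr::local_tempfile(fileext = ".bed")
  write_bed(gr, path)
  back <- read_bed(path, toy_layout)
  expect_equal(start(back), start(gr))
  expect_equal(end(back), end(gr))
  expect_equal(mcols(back)$name, mcols(gr)$name)
  # '*' is written as '.' and read back as '*'
  expect_equal(as.character(strand(back)), as.character(strand(gr)))
  # and the file itself is stable under a second round-trip
  path2 <- withr::local_tempfile(fileext = ".bed")
  write_bed(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("narrowPeak summits are resolved, imputed and validated", {
  path <- withr::local_tempfile(fileext = ".narrowPeak")
  writeLines("chr1\t100\t350\tp1\t0\t.\t5\t3\t2\t125", path)
  pk <- read_narrowpeak(path)
  expect_equal(mcols(pk)$summit, 226L)  # 0-based 100 + 125 = 225
  expect_false(mcols(pk)$summit_imputed)

  writeLines("chr1\t100\t350\tp1\t0\t.\t5\t3\t2\t-1", path)
  pk <- read_narrowpeak(path)
  expect_equal(mcols(pk)$summit, 226L)  # midpoint floor((100+350)/2) = 225
  expect_true(mcols(pk)$summit_imputed)

  writeLines("chr1\t100\t350\tp1\t0\t.\t5\t3\t2\t300", path)
  expect_error(read_narrowpeak(path), "summit offset 300")
})

test_that("pairwise overlap follows half-open logic", {
  expect_true(ranges_overlap(gr0("chr1", 10, 20), gr0("chr1", 19, 30)))
  expect_false(ranges_overlap(gr0("chr1", 10, 20), gr0("chr1", 20, 30)))
  expect_false(ranges_overlap(gr0("chr1", 10, 20), gr0("chr2", 10, 20)))
})

test_that("members_overlapping matches examples and brute force", {
  q <- gr0(c("chr1", "chr1"), c(0, 50), c(10, 60))
  s <- gr0("chr1", 5, 6)
  expect_equal(granges(members_overlapping(q, s)), granges(q[1]))
  expect_length(members_overlapping(q, GRanges()), 0)

  set.seed(11)
  for (i in 1:25) {
    q <- random_intervals(sample.int(200, 1), toy_layout)
    s <- random_intervals(sample.int(200, 1), toy_layout)
    expect_identical(granges(members_overlapping(q, s)),
                     granges(brute_members_overlapping(q, s)))
  }
})

test_that("summit extension yields centered, clipped windows", {
  pk <- with_summit0(gr0("chr1", 400, 700, layout = toy_layout), 500)
  win <- extend_about_summit(pk, 125)
  expect_equal(start(win) - 1L, 375)  # 0-based [375, 626)
  expect_equal(end(win), 626)
  expect_equal(width(win), 251)

  low <- with_summit0(gr0("chr1", 0, 200, layout = toy_layout), 50)
  win <- extend_about_summit(low, 125)
  expect_equal(start(win), 1L)        # clipped to 0-based [0, 176)
  expect_equal(end(win), 176)

  expect_equal(width(extend_about_summit(pk, 0)), 1)
  expect_equal(width(extend_about_summit(pk, 125, include_summit = FALSE)),
               250)
  # never escapes the chromosome
  set.seed(3)
  pks <- random_intervals(100, toy_layout)
  s <- start(pks) + floor(runif(100) * width(pks))
  mcols(pks)$summit <- as.integer(s)
  win <- extend_about_summit(pks, 500)
  expect_true(all(start(win) >= 1))
  expect_true(all(end(win) <= seqlengths(toy_layout)[
    as.character(seqnames(win))]))
})

test_that("upstream windows honor strand and clip at chromosome start", {
  plus <- gr0("chr1", 1000, 1001, strand = "+", layout = toy_layout)
  w <- upstream_window(plus, 200)
  expect_equal(c(start(w) - 1L, end(w)), c(800, 1000))  # [800, 1000)

  minus <- gr0("chr1", 1000, 1001, strand = "-", layout = toy_layout)
  w <- upstream_window(minus, 200)
  expect_equal(c(start(w) - 1L, end(w)), c(1001, 1201))  # [1001, 1201)

  near <- gr0("chr1", 100, 101, strand = "+", layout = toy_layout)
  w <- upstream_window(near, 200)
  expect_equal(c(start(w) - 1L, end(w)), c(0, 100))      # clipped

  expect_error(upstream_window(gr0("chr1", 1000, 1001)), "stranded")
})

test_that("fetch_sequence extracts and reverse-complements", {
  genome <- Biostrings::DNAStringSet(c(chr1 = "ACGTACGT"))
  expect_equal(fetch_sequence(gr0("chr1", 2, 5), genome), "GTA")
  expect_equal(fetch_sequence(gr0("chr1", 2, 5, strand = "-"), genome),
               "TAC")
  expect_error(fetch_sequence(gr0("chr1", 2, 12), genome), "bounds")
  expect_error(fetch_sequence(gr0("chrX", 0, 2), genome), "absent")
})

test_that("genome layout validates names and lengths", {
  expect_error(genome_layout(c(100, 200)), "unique")
  expect_error(genome_layout(c(chr1 = 100, chr1 = 200)), "unique")
  expect_error(genome_layout(c(chr1 = 0)), "positive")
  layout <- genome_layout(c(chr1 = 500))
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t400\t600", path)
  expect_error(read_bed(path, layout), "beyond")
  writeLines("chrZ\t0\t10", path)
  expect_error(read_bed(path, layout), "absent")
})
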