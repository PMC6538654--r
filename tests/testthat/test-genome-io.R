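write_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

test_that("FASTA reading preserves order, upper-cases and validates", {
  f <- write_tmp(c(">chr1 some description", "acgt", ">chr2", "NNAC"),
                 ".fa")
  g <- read_fasta(f)
  expect_s3_class(g, "censcape_genome")
  expect_identical(names(g$chromosomes), c("chr1", "chr2"))
  expect_identical(unname(g$lengths), c(4L, 4L))
  expect_identical(g$chromosomes[["chr1"]], "ACGT")
  expect_identical(g$chromosomes[["chr2"]], "NNAC")

  expect_error(read_fasta(write_tmp(character(0), ".fa")), "no records")
  expect_error(read_fasta(write_tmp(c(">a", "ACGT", ">a", "TT"), ".fa")),
               "duplicate.*a")
  expect_error(read_fasta(write_tmp(c(">a", "ACXGT"), ".fa")),
               "position 3")
})

test_that("BED intervals are read 0-based half-open with validation", {
  f <- write_tmp("chr1\t100\t200\tpeak\t0\t+")
  x <- read_intervals(f, "bed")
  expect_identical(x$chrom, "chr1")
  expect_identical(x$start, 100L)
  expect_identical(x$end, 200L)
  expect_identical(x$name, "peak")
  expect_identical(x$strand, "+")

  x3 <- read_intervals(write_tmp("chr1\t5\t10"), "bed")
  expect_identical(x3$strand, ".")

  # 5-column files with the strand in place of the score are tolerated
  x5 <- read_intervals(write_tmp("chr1\t100\t200\tpeak\t+"), "bed")
  expect_identical(x5$strand, "+")
  expect_identical(x5$score, 0L)

  expect_error(read_intervals(write_tmp("chr1\t200\t100"), "bed"),
               "line 1.*start >= end")
  expect_error(
    read_intervals(write_tmp(c("chr1\t1\t2", "chr1\t9\t9")), "bed"),
    "line 2"
  )
})

test_that("GFF3 coordinates convert to 0-based half-open", {
  f <- write_tmp(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t101\t200\t.\t+\t.\tID=g1;Name=tRNA-D"
  ), ".gff3")
  x <- read_intervals(f, "gff3")
  expect_identical(x$start, 100L)
  expect_identical(x$end, 200L)
  expect_identical(x$strand, "+")
  expect_identical(x$name, "tRNA-D")
})

test_that("BED write/read round-trips the six standard columns", {
  x <- tibble::tibble(
    chrom = c("chr1", "chr2"), start = c(100L, 0L), end = c(200L, 50L),
    name = c("a", "b"), score = c(5L, 0L), strand = c("+", "-")
  )
  f <- tempfile(fileext = ".bed")
  write_intervals(x, f)
  expect_identical(read_intervals(f, "bed"), x)
})

test_that("windowing emits only full-length windows from position 0", {
  g <- coord_genome(19500)
  w <- make_windows(g)
  expect_identical(w$start, c(0L, 7500L))
  expect_identical(w$end, c(12000L, 19500L))
  expect_identical(w$index, c(1L, 2L))

  expect_identical(nrow(make_windows(coord_genome(12000))), 1L)
  expect_identical(nrow(make_windows(coord_genome(11999))), 0L)
  expect_error(make_windows(g, window_len = 100, overlap = 100), "overlap")
})

test_that("window count matches the closed-form tiling formula", {
  wl <- 120; ov <- 45; step <- wl - ov
  for (L in c(50, 119, 120, 121, 500, 1234, 7777)) {
    w <- make_windows(coord_genome(L), window_len = wl, overlap = ov)
    expected <- max(0, floor((L - wl) / step) + 1)
    expect_identical(nrow(w), as.integer(expected))
    # direct enumeration: every start s with s + wl <= L on the grid
    starts <- seq(0, max(0, L), by = step)
    expect_identical(w$start, as.integer(starts[starts + wl <= L]))
  }
})

test_that("interval coverage is a clipped union", {
  win <- tibble::tibble(chrom = "chr1", start = 0L, end = 12000L)
  peaks <- tibble::tibble(chrom = "chr1", start = c(1000L, 3000L),
                          end = c(4000L, 8000L))
  expect_identical(interval_coverage(win, peaks), 7000L)
  expect_identical(interval_coverage(win, peaks[0, ]), 0L)
  expect_identical(
    interval_coverage(win, tibble::tibble(chrom = "chr1", start = 11000L,
                                          end = 13000L)),
    1000L
  )
  # other-chromosome peaks do not count
  expect_identical(
    interval_coverage(win, tibble::tibble(chrom = "chr9", start = 0L,
                                          end = 500L)),
    0L
  )
})

test_that("coverage is invariant to peak order and abutting splits", {
  set.seed(11)
  win <- tibble::tibble(chrom = "chr1", start = 0L, end = 5000L)
  for (rep in 1:20) {
    n <- sample(1:6, 1)
    s <- sort(sample(0:6000, n))
    e <- s + sample(50:1500, n, replace = TRUE)
    peaks <- tibble::tibble(chrom = "chr1", start = s, end = as.integer(e))
    base <- interval_coverage(win, peaks)
    expect_identical(interval_coverage(win, peaks[sample(n), ]), base)
    # split each peak into two abutting pieces
    mid <- as.integer(floor((peaks$start + peaks$end) / 2))
    split <- tibble::tibble(
      chrom = "chr1",
      start = c(peaks$start, mid), end = c(mid, peaks$end)
    )
    split <- split[split$start < split$end, ]
    expect_identical(interval_coverage(win, split), base)
  }
})
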