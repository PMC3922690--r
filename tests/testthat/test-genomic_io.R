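test_that("BED6 and BED3 records parse with defaults, preserving file order", {
  bed <- write_bed(c(
    "track name=test",
    "chr1\t100\t300\tp1\t0\t+",
    "chr2\t0\t50",
    "# a comment",
    "chr1\t500\t900\tp2\t3.5\t-"))
  gr <- read_regions(bed)
  expect_equal(length(gr), 3L)
  expect_equal(names(gr), c("p1", "locus_2", "p2"))
  expect_equal(as.character(GenomicRanges::seqnames(gr)),
               c("chr1", "chr2", "chr1"))
  # 0-based half-open input -> 1-based closed GRanges
  expect_equal(GenomicRanges::start(gr), c(101L, 1L, 501L))
  expect_equal(GenomicRanges::end(gr), c(300L, 50L, 900L))
  expect_equal(as.character(GenomicRanges::strand(gr)), c("+", "*", "-"))
  expect_equal(gr$score[3], 3.5)
})

test_that("malformed coordinates are rejected with a line diagnostic", {
  bed <- write_bed(c(
    "chr1\t10\t20\ta",
    "chr1\t30\t40\tb",
    "chr1\t50\t50\tbad",
    "chr1\t60\t70\tc"))
  expect_warning(gr <- read_regions(bed), "line 3")
  expect_equal(length(gr), 3L)
  expect_equal(names(gr), c("a", "b", "c"))

  expect_error(read_regions(write_bed(character(0))), "empty")
  expect_error(suppressWarnings(read_regions(write_bed("chr1\t9\t5\tx"))),
               "no valid")
})

test_that("duplicate locus names are suffixed to stay unique", {
  bed <- write_bed(c("chr1\t0\t10\tdup", "chr1\t20\t30\tdup"))
  gr <- read_regions(bed)
  expect_equal(anyDuplicated(names(gr)), 0L)
  expect_equal(names(gr)[1], "dup")
})

test_that("read counting matches a brute-force overlap scan and the fixture truth", {
  td <- file.path(tempdir(), "io_abs")
  fx <- make_toy_alignments("absolute", td)
  gr <- read_regions(fx$bed)
  starts0 <- GenomicRanges::start(gr) - 1L
  ends0 <- GenomicRanges::end(gr)
  M <- build_count_matrix(fx$bams, gr)
  for (mk in colnames(M)) {
    oracle <- brute_force_counts(fx$bams[[mk]], starts0, ends0)
    expect_equal(unname(M[, mk]), oracle)
  }
  truth <- as.matrix(fx$truth[, c("mark1", "mark2", "mark3")])
  expect_equal(unname(M), unname(truth))
})

test_that("a read spanning adjacent loci contributes to both", {
  td <- file.path(tempdir(), "io_adj")
  dir.create(td, showWarnings = FALSE)
  # 36 bp reads at 0-based starts 150 ([150,186)), 290 ([290,326)), 400
  bam <- chromcode:::.write_toy_bam(c(150L, 290L, 400L),
                                    file.path(td, "adj"))
  gr <- read_regions(write_bed(c("chrS\t100\t300\tp1",
                                 "chrS\t300\t500\tp2")))
  counts <- count_reads(bam, gr)
  expect_equal(unname(counts["p1"]), 2L)   # reads at 150 and 290
  expect_equal(unname(counts["p2"]), 2L)   # read at 290 spans the boundary
})

test_that("windowed counts tile loci exactly and re-count boundary reads", {
  td <- file.path(tempdir(), "io_win")
  dir.create(td, showWarnings = FALSE)
  bam <- chromcode:::.write_toy_bam(95L, file.path(td, "win"))  # [95,131)
  gr <- read_regions(write_bed("chrS\t0\t250\tL"))
  wc <- windowed_counts(bam, gr, window = 100)
  expect_equal(length(wc$L), 3L)            # [0,100), [100,200), [200,250)
  expect_equal(wc$L, c(1L, 1L, 0L))         # straddling read counted twice
  expect_gte(sum(wc$L), unname(count_reads(bam, gr)))
  # tiling loses no bases
  tiles <- GenomicRanges::slidingWindows(gr, 100L, 100L)[[1]]
  expect_equal(sum(GenomicRanges::width(tiles)), 250L)
})

test_that("chromosomes absent from the BAM header count zero with a warning", {
  td <- file.path(tempdir(), "io_missing")
  dir.create(td, showWarnings = FALSE)
  bam <- chromcode:::.write_toy_bam(100L, file.path(td, "m"))
  gr <- read_regions(write_bed(c("chrS\t50\t200\tok", "chrX\t0\t100\tgone")))
  expect_warning(counts <- count_reads(bam, gr), "chrX")
  expect_equal(unname(counts), c(1L, 0L))
})

test_that("count matrices refuse duplicate mark labels", {
  td <- file.path(tempdir(), "io_dup")
  dir.create(td, showWarnings = FALSE)
  bam <- chromcode:::.write_toy_bam(100L, file.path(td, "d"))
  gr <- read_regions(write_bed("chrS\t50\t200\tL"))
  expect_error(build_count_matrix(c(bam, bam), gr, labels = c("x", "x")),
               "duplicate")
})
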