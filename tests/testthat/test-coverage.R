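test_that("bins tile each chromosome exactly, keeping a short last bin", {
  gb <- make_bins(c(chr1 = 1000L), bin_width = 200L)
  expect_equal(nrow(gb$bins), 5L)
  expect_equal(gb$bins$start, seq(0L, 800L, by = 200L))
  expect_equal(gb$bins$end, seq(200L, 1000L, by = 200L))
  expect_equal(gb$mappable_bp, rep(200, 5))

  gb2 <- make_bins(c(chr1 = 1001L), bin_width = 200L)
  expect_equal(nrow(gb2$bins), 6L)
  expect_equal(gb2$bins$start[6], 1000L)
  expect_equal(gb2$bins$end[6], 1001L)
  expect_equal(gb2$mappable_bp[6], 1)

  # tiling completeness over several chromosomes
  sizes <- c(a = 1234L, b = 999L, c = 200L)
  gb3 <- make_bins(sizes, bin_width = 200L)
  lens <- tapply(gb3$bins$end - gb3$bins$start, gb3$bins$chrom, sum)
  expect_equal(as.numeric(lens[names(sizes)]), as.numeric(sizes))
  expect_equal(gb3$genome_mappable, sum(as.numeric(sizes)))
})

test_that("mappability track reduces M(j) and G", {
  map <- GenomicRanges::GRanges("chr1",
                                IRanges::IRanges(start = 1, end = 100),
                                score = 1)
  GenomeInfoDb::seqlengths(map) <- c(chr1 = 1000L)
  gb <- make_bins(c(chr1 = 1000L), bin_width = 200L, mappability = map)
  expect_equal(gb$mappable_bp, c(100, 0, 0, 0, 0))
  expect_equal(gb$genome_mappable, 100)

  badmap <- GenomicRanges::GRanges("chrX", IRanges::IRanges(1, 10),
                                   score = 1)
  expect_error(make_bins(c(chr1 = 1000L), mappability = badmap), "chrX")
  expect_error(make_bins(data.frame(chrom = character(),
                                    length = integer())),
               "empty")
})

test_that("read loading extends 3'-ward, clips, dedups and tallies", {
  sizes <- toy_chrom_sizes()
  bed <- data.frame(
    chrom = c("chrT1", "chrT1", "chrT1", "chrT1", "chrT1", "chrUnknown"),
    start = c(100L, 100L, 300L, 300L, 500L, 10L),
    end   = c(136L, 136L, 336L, 250L, 400L, 50L),
    name = ".", score = 0L,
    strand = c("+", "-", "+", "+", "+", "+")
  )
  bed$end[4] <- 250L
  path <- write_bed(bed)
  expect_warning(
    rs <- load_reads(path, mark = "H3K27ac", chrom_sizes = sizes,
                     extension_bp = 200L),
    "chromosomes absent"
  )
  iv <- rs$intervals
  # '+' read (100,136) -> (100,300); '-' read (100,136) -> (-64 -> 0,136)
  expect_equal(unlist(iv[1, c("start", "end")], use.names = FALSE),
               c(100, 300))
  expect_equal(unlist(iv[2, c("start", "end")], use.names = FALSE),
               c(0, 136))
  expect_equal(rs$n_unknown_chrom, 1L)
  # rows 4 (end < start) and 5 (end < start) are malformed
  expect_equal(rs$n_malformed, 2L)
  expect_equal(rs$total_mapped, 3L)

  # malformed (start >= end) records skipped with a tally
  bad <- rbind(bed[1:2, ], data.frame(chrom = "chrT1", start = 700L,
                                      end = 600L, name = ".", score = 0L,
                                      strand = "+"))
  rs2 <- load_reads(write_bed(bad), mark = "m", chrom_sizes = sizes)
  expect_equal(rs2$n_malformed, 1L)
  expect_equal(rs2$total_mapped, 2L)

  # exact duplicates removed only under dedup
  dup <- bed[c(1, 1, 1), ]
  rs3 <- load_reads(write_bed(dup), mark = "m", chrom_sizes = sizes,
                    dedup = TRUE)
  expect_equal(rs3$total_mapped, 1L)
  expect_equal(rs3$n_duplicates, 2L)
  rs4 <- load_reads(write_bed(dup), mark = "m", chrom_sizes = sizes,
                    dedup = FALSE)
  expect_equal(rs4$total_mapped, 3L)

  # strandless records default to '+'
  nostrand <- bed[1:2, 1:3]
  expect_message(
    rs5 <- load_reads(write_bed(nostrand), mark = "m",
                      chrom_sizes = sizes, extension_bp = 200L),
    "without strand"
  )
  expect_equal(rs5$intervals$strand, c("+", "+"))

  # reads already >= extension_bp stay unchanged
  long <- data.frame(chrom = "chrT1", start = 0L, end = 400L, name = ".",
                     score = 0L, strand = "+")
  rs6 <- load_reads(write_bed(long), mark = "m", chrom_sizes = sizes,
                    extension_bp = 200L)
  expect_equal(rs6$intervals$end, 400)

  # 'by' dialect extends by extension_bp
  rs7 <- load_reads(write_bed(bed[1, ]), mark = "m", chrom_sizes = sizes,
                    extension_bp = 200L, extension_mode = "by")
  expect_equal(rs7$intervals$end, 336)
})

test_that("reads increment every overlapped bin", {
  sizes <- toy_chrom_sizes()
  gb <- make_bins(sizes, bin_width = 200L)
  bed <- data.frame(chrom = "chrT1",
                    start = c(0L, 150L), end = c(200L, 350L),
                    name = ".", score = 0L, strand = "+")
  rs <- load_reads(write_bed(bed), mark = "m", chrom_sizes = sizes,
                   extension_bp = 0L)
  cnt <- count_reads(rs, gb)
  # read 1 only in bin 1; read 2 spans bins 1 and 2
  expect_equal(cnt[1:3], c(2L, 1L, 0L))
  expect_true(all(cnt[-(1:2)] == 0L))

  empty <- load_reads(write_bed(bed[0, ]), mark = "m",
                      chrom_sizes = sizes)
  expect_equal(sum(count_reads(empty, gb)), 0L)
})

test_that("expected counts implement both normalization modes", {
  gb <- make_bins(c(chr1 = 1000L), bin_width = 200L)
  mk_rs <- function(n, sample) {
    structure(list(mark = "m", sample = sample,
                   intervals = data.frame(
                     chrom = rep("chr1", n),
                     start = rep(10L, n), end = rep(60L, n),
                     strand = rep("+", n)),
                   total_mapped = n, n_malformed = 0L,
                   n_unknown_chrom = 0L, n_duplicates = 0L,
                   n_unstranded = 0L), class = "read_set")
  }
  # uniform: C=500, M=200, G=1000 -> E = 100
  ct <- expected_counts(gb, list(mk_rs(500L, "r1")), mode = "uniform")
  expect_equal(unname(ct$expected[1, 1]), 100)
  # literal: Q = A/C = 1000/500 = 2 -> E = 200/(1000*2) = 0.1
  ct2 <- expected_counts(gb, list(mk_rs(500L, "r1"), mk_rs(1500L, "r2")),
                         mode = "literal")
  expect_equal(unname(ct2$scale), c(2, 2 / 3))
  expect_equal(unname(ct2$expected[1, 1]), 200 / (1000 * 2))
  # identical replicates give Q = 1
  ct3 <- expected_counts(gb, list(mk_rs(500L, "r1"), mk_rs(500L, "r2")))
  expect_equal(unname(ct3$scale), c(1, 1))
  # zero-depth replicate rejected
  expect_error(expected_counts(gb, list(mk_rs(0L, "r1"))), "zero mapped")
})

test_that("normalized coverage is the ratio of summed counts to expectations", {
  gb <- make_bins(c(chr1 = 1000L), bin_width = 200L)
  ct <- structure(list(
    counts = matrix(c(30, 0, 10, 0, 0), ncol = 1),
    expected = matrix(c(10, 10, 10, 10, 10), ncol = 1),
    scale = 1, dataset_mean = 50, mark = "m", mode = "uniform",
    bins = gb), class = "count_tensor")
  s <- normalized_coverage_vector(ct)
  expect_equal(as.numeric(s), c(3, 0, 1, 0, 0))

  # unmappable bins get coverage 0 and a flag
  ct$expected[2, 1] <- 0
  s2 <- normalized_coverage_vector(ct)
  expect_equal(s2[[2]], 0)
  expect_true(attr(s2, "unmappable")[2])
})

test_that("uniform random reads give mean coverage near 1 and scaling neutrality", {
  sizes <- c(chrT1 = 200000L)
  gb <- make_bins(sizes, bin_width = 200L)
  n_reads <- 20000L
  # width-1 reads so each read falls in exactly one bin (multi-bin
  # assignment otherwise inflates the mean by design)
  bed <- withr::with_seed(7L, {
    start <- sample.int(200000L, n_reads, replace = TRUE) - 1L
    data.frame(chrom = "chrT1", start = start, end = start + 1L,
               name = ".", score = 0L, strand = "+")
  })
  rs <- load_reads(write_bed(bed), mark = "m", chrom_sizes = sizes,
                   extension_bp = 0L)
  V <- normalized_coverage(gb, list(m = list(rs)))
  s <- V$values[, 1]
  se <- stats::sd(s) / sqrt(length(s))
  expect_lt(abs(mean(s) - 1), 3 * se)

  # duplicating every read doubles R and C (hence E); S is invariant
  rs2 <- load_reads(write_bed(rbind(bed, bed)), mark = "m",
                    chrom_sizes = sizes, extension_bp = 0L)
  V2 <- normalized_coverage(gb, list(m = list(rs2)))
  expect_equal(V2$values, V$values)
})

test_that("bedGraph export round-trips nonzero coverage", {
  gb <- make_bins(c(chr1 = 1000L), bin_width = 200L)
  V <- coverage_matrix(matrix(c(0, 1.5, 0, 2.25, 3), ncol = 1,
                              dimnames = list(NULL, "m1")),
                       bins = gb$bins)
  f <- tempfile(fileext = ".bedGraph")
  write_coverage_bedgraph(V, "m1", f)
  back <- rtracklayer::import(f, format = "bedGraph")
  expect_equal(length(back), 3L)
  expect_equal(back$score, c(1.5, 2.25, 3))
  expect_equal(GenomicRanges::start(back) - 1L, c(200L, 600L, 800L))
})

test_that("coverage matrices survive a TSV round trip", {
  gb <- make_bins(c(chr1 = 1000L), bin_width = 200L)
  V <- coverage_matrix(matrix(c(0.5, 1.25, 0, 3, 7, 2.125, 0.1, 0, 9, 4),
                              ncol = 2,
                              dimnames = list(NULL, c("m1", "m2"))),
                       bins = gb$bins)
  f <- tempfile(fileext = ".tsv")
  write_coverage_tsv(V, f)
  V2 <- read_coverage_tsv(f)
  expect_equal(V2$values, V$values)
  expect_equal(V2$bins, V$bins)
})
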