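test_that("BED fragments parse with 0-based half-open semantics", {
  p <- withr::local_tempfile(lines = c("chrI\t100\t250",
                                       "chrI\t0\t2",
                                       "not a bed line",
                                       "chrII\t500\t650"))
  expect_warning(fr <- read_fragments(p), "malformed")
  expect_equal(length(fr), 3)
  expect_equal(BiocGenerics::start(fr)[1], 101)  # 1-based internal
  expect_equal(BiocGenerics::end(fr)[1], 250)
  expect_equal(BiocGenerics::width(fr)[1], 150)

  pe <- withr::local_tempfile(lines = character())
  expect_warning(fre <- read_fragments(pe), "empty")
  expect_equal(length(fre), 0)
})

test_that("simulator fragments survive a BED round trip at full depth", {
  cfg <- tiny_config(seed = 21, n_genes = 8, frags_per_nuc = 25)
  genome <- build_toy_genome(cfg)
  fr <- sample_fragments(place_arrays(genome, cfg), cfg,
                         genome$chrom_sizes)
  p <- withr::local_tempfile(fileext = ".bed")
  write_fragments_bed(fr, p)
  fr2 <- read_fragments(p)
  expect_equal(length(fr2), cfg$depth)
  expect_equal(BiocGenerics::start(fr2), BiocGenerics::start(fr))
  expect_equal(BiocGenerics::end(fr2), BiocGenerics::end(fr))
})

test_that("BAM ingestion counts each proper pair once", {
  skip_if_not_installed("Rsamtools")
  sam <- c("@HD\tVN:1.6\tSO:coordinate",
           "@SQ\tSN:chrT\tLN:10000",
           # proper pair: fragment chrT:101-250 (1-based), isize 150
           "r1\t99\tchrT\t101\t60\t50M\t=\t201\t150\t*\t*",
           "r1\t147\tchrT\t201\t60\t50M\t=\t101\t-150\t*\t*",
           # second proper pair
           "r2\t99\tchrT\t501\t60\t50M\t=\t551\t100\t*\t*",
           "r2\t147\tchrT\t551\t60\t50M\t=\t501\t-100\t*\t*")
  samf <- withr::local_tempfile(lines = sam, fileext = ".sam")
  bam <- Rsamtools::asBam(samf, withr::local_tempfile(),
                          overwrite = TRUE, indexDestination = FALSE)
  fr <- read_fragments(bam)
  expect_equal(length(fr), 2)
  expect_equal(BiocGenerics::start(fr), c(101, 501))
  expect_equal(BiocGenerics::width(fr), c(150, 100))

  # unpaired BAM: advise BED input
  sam_u <- c("@HD\tVN:1.6\tSO:coordinate", "@SQ\tSN:chrT\tLN:10000",
             "r1\t0\tchrT\t101\t60\t50M\t*\t0\t0\t*\t*")
  samfu <- withr::local_tempfile(lines = sam_u, fileext = ".sam")
  bam_u <- Rsamtools::asBam(samfu, withr::local_tempfile(),
                            overwrite = TRUE, indexDestination = FALSE)
  expect_error(read_fragments(bam_u), "BED")
})

test_that("size selection keeps the closed 140-160 interval", {
  fr <- GenomicRanges::GRanges("chrT", IRanges::IRanges(
    start = 1, width = c(139, 140, 150, 160, 161)))
  kept <- filter_by_length(fr)
  expect_equal(BiocGenerics::width(kept), c(140, 150, 160))
  expect_equal(length(filter_by_length(fr, 0, Inf)), 5)
  expect_error(filter_by_length(fr, 200, 100), "min_len")
})

test_that("kept fraction under size selection matches the normal CDF mass", {
  cfg <- tiny_config(seed = 31, n_genes = 20, frags_per_nuc = 100)
  genome <- build_toy_genome(cfg)
  fr <- sample_fragments(place_arrays(genome, cfg), cfg,
                         genome$chrom_sizes)
  kept <- length(filter_by_length(fr)) / length(fr)
  # integer lengths: mass of N(151,6) on [139.5, 160.5], renormalized to
  # the rejection bounds [119.5, 200.5]
  p <- (pnorm(160.5, 151, 6) - pnorm(139.5, 151, 6)) /
    (pnorm(200.5, 151, 6) - pnorm(119.5, 151, 6))
  expect_lt(abs(kept - p), 3 * sqrt(p * (1 - p) / length(fr)))
})

test_that("exclusion removes any-overlap fragments, half-open boundaries", {
  fr <- GenomicRanges::GRanges("chrXII", IRanges::IRanges(
    start = c(450901, 469001, 460001), end = c(451050, 469150, 460150)))
  out <- exclude_regions(fr, rdna_region())
  # overlapping and contained fragments go; the one starting exactly at
  # the half-open end (0-based 469000) stays
  expect_equal(BiocGenerics::start(out), 469001)
  expect_identical(exclude_regions(fr, GenomicRanges::GRanges()), fr)
})

test_that("subsampling is exact-count, seed-deterministic and order-safe", {
  fr <- GenomicRanges::GRanges("chrT", IRanges::IRanges(
    start = seq(1, 100000, by = 10), width = 150))
  expect_equal(length(subsample_fragments(fr, 0, seed = 1)), 0)
  expect_warning(all_of <- subsample_fragments(fr, length(fr) + 10, seed = 1),
                 "available")
  expect_identical(all_of, fr)

  s1 <- subsample_fragments(fr, 500, seed = 42)
  s2 <- subsample_fragments(fr, 500, seed = 42)
  s3 <- subsample_fragments(fr, 500, seed = 43)
  expect_identical(s1, s2)
  expect_equal(length(s1), 500)
  expect_false(identical(BiocGenerics::start(s1), BiocGenerics::start(s3)))
})

test_that("pipeline order filter/exclude commutes before subsampling", {
  cfg <- tiny_config(seed = 51, n_genes = 10, frags_per_nuc = 40)
  genome <- build_toy_genome(cfg)
  fr <- sample_fragments(place_arrays(genome, cfg), cfg,
                         genome$chrom_sizes)
  excl <- GenomicRanges::GRanges("chrS1", IRanges::IRanges(5001, 9000))
  a <- subsample_fragments(exclude_regions(filter_by_length(fr), excl),
                           1000, seed = 9)
  b <- subsample_fragments(filter_by_length(exclude_regions(fr, excl)),
                           1000, seed = 9)
  expect_identical(BiocGenerics::start(a), BiocGenerics::start(b))
  expect_identical(BiocGenerics::end(a), BiocGenerics::end(b))
})

test_that("fragment dyads are floor midpoints", {
  fr <- GenomicRanges::GRanges("chrT", IRanges::IRanges(
    start = c(101, 101, 1), end = c(250, 251, 2)))
  expect_equal(fragment_dyad(fr), c(175, 175, 1))
})

test_that("dyad tracks conserve coverage and clip at edges", {
  cs <- c(chrT = 100000L)
  one <- GenomicRanges::GRanges("chrT", IRanges::IRanges(101, 250))
  tr <- build_dyad_track(one, cs)  # dyad 175
  v <- as.numeric(tr$coverage$chrT)
  expect_equal(sum(v), 101)
  expect_true(all(v[126:226] == 1))  # 0-based 125..225
  expect_true(all(v[-(126:226)] == 0))

  edge <- GenomicRanges::GRanges("chrT", IRanges::IRanges(1, 21))  # dyad 10
  expect_equal(track_sum(build_dyad_track(edge, cs)), 61)

  cfg <- tiny_config(seed = 61, n_genes = 5, frags_per_nuc = 25)
  genome <- build_toy_genome(cfg)
  fr <- sample_fragments(place_arrays(genome, cfg), cfg,
                         genome$chrom_sizes)
  fr <- fr[1:1000]
  tr2 <- build_dyad_track(fr, genome$chrom_sizes)
  expect_equal(track_sum(tr2), 1000 * 101)
  expect_equal(tr2$n_fragments_used, 1000)

  expect_error(build_dyad_track(one, c(chrX = 1000L)), "chrT")
})

test_that("translation equivariance of the track away from edges", {
  cs <- c(chrT = 50000L)
  fr <- GenomicRanges::GRanges("chrT", IRanges::IRanges(
    start = c(1001, 2001, 3001), width = 150))
  delta <- 500L
  tr0 <- as.numeric(build_dyad_track(fr, cs)$coverage$chrT)
  trd <- as.numeric(build_dyad_track(GenomicRanges::shift(fr, delta),
                                     cs)$coverage$chrT)
  n <- length(tr0)
  expect_equal(trd[(delta + 1):n], tr0[1:(n - delta)])
})

test_that("bedGraph writing is run-length exact and lossless", {
  # constructed track [0,0,2,2,1]
  tr <- track_from_vector(c(0, 0, 2, 2, 1))
  p <- withr::local_tempfile(fileext = ".bedGraph")
  write_track(tr, p)
  expect_equal(readLines(p), c("chrT\t2\t4\t2", "chrT\t4\t5\t1"))

  # all-zero body is empty
  p0 <- withr::local_tempfile(fileext = ".bedGraph")
  write_track(track_from_vector(numeric(10)), p0)
  expect_equal(length(readLines(p0)), 0)

  # simulated round trip, elementwise
  cfg <- tiny_config(seed = 71, n_genes = 5, frags_per_nuc = 25)
  genome <- build_toy_genome(cfg)
  fr <- sample_fragments(place_arrays(genome, cfg), cfg,
                         genome$chrom_sizes)
  tr2 <- build_dyad_track(filter_by_length(fr), genome$chrom_sizes)
  p2 <- withr::local_tempfile(fileext = ".bedGraph")
  write_track(tr2, p2)
  tr3 <- read_track(p2, genome$chrom_sizes)
  expect_equal(as.numeric(tr3$coverage[[1]]), as.numeric(tr2$coverage[[1]]))
})
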