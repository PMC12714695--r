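test_that("read extension follows strand for treatments and midpoint for controls", {
  sl <- c(chr1 = 10000L)
  plus <- GRanges("chr1", IRanges(1001, width = 50), strand = "+",
                  seqlengths = sl)
  ext <- extend_reads(plus, 200, "treatment")
  expect_equal(start(ext), 1001)
  expect_equal(end(ext), 1200)

  minus <- GRanges("chr1", IRanges(1151, 1200), strand = "-", seqlengths = sl)
  ext <- extend_reads(minus, 200, "treatment")
  expect_equal(start(ext), 1001)
  expect_equal(end(ext), 1200)

  ctrl <- GRanges("chr1", IRanges(1051, 1150), strand = "+", seqlengths = sl)
  ext <- extend_reads(ctrl, 200, "control")
  expect_equal(width(ext), 200)
  expect_equal(start(ext) + end(ext), 1051 + 1150)  # midpoint preserved

  # extension past the chromosome end clips, never errors
  edge <- GRanges("chr1", IRanges(9951, 10000), strand = "+", seqlengths = sl)
  ext <- extend_reads(edge, 200, "treatment")
  expect_equal(end(ext), 10000)
})

test_that("library normalization weights sum to the 25-million target", {
  sl <- c(chr1 = 1e6L)
  reads <- GRanges("chr1", IRanges(seq(1, 5e5, length.out = 50000), width = 50),
                   seqlengths = sl)
  w <- normalize_library(reads)
  expect_equal(unique(w$weight), 25e6 / 50000)
  expect_identical(sum(w$weight), 25e6)
  expect_equal(normalize_library(reads, target = length(reads))$weight[1], 1)
  expect_error(normalize_library(reads[0]), "empty")
})

test_that("bin coverage equals the base-pair pileup averaged per bin", {
  sl <- c(chr1 = 2000L)
  bins <- genome_bins(sl, 200)

  one <- GRanges("chr1", IRanges(201, 400), seqlengths = sl)
  v <- bin_coverage(one, bins)
  expect_equal(as.numeric(v), c(0, 1, rep(0, 8)))

  straddle <- GRanges("chr1", IRanges(351, 550), seqlengths = sl)
  v <- bin_coverage(straddle, bins)
  expect_equal(v[2:3], c(50 / 200, 150 / 200))

  # oracle: explicit per-base pileup, averaged over each bin
  set.seed(7)
  n <- 1000
  gr <- GRanges("chr1", IRanges(sample(1900, n, replace = TRUE),
                                width = sample(30:120, n, replace = TRUE)),
                seqlengths = sl)
  gr <- suppressWarnings(trim(gr))
  mcols(gr)$weight <- runif(n, 0.5, 2)
  pileup <- numeric(2000)
  for (i in seq_len(n)) {
    idx <- start(gr)[i]:end(gr)[i]
    pileup[idx] <- pileup[idx] + gr$weight[i]
  }
  oracle <- vapply(seq_along(bins), function(b)
    mean(pileup[start(bins)[b]:end(bins)[b]]), numeric(1))
  expect_equal(as.numeric(bin_coverage(gr, bins)), oracle, tolerance = 1e-12)

  # reads on unknown chromosomes are skipped, not an error
  odd <- suppressWarnings(c(gr, GRanges("chrUn", IRanges(1, 50), weight = 1)))
  v <- suppressWarnings(bin_coverage(odd, bins))
  expect_equal(attr(v, "n_skipped"), 1L)
})

test_that("binning conserves read mass and commutes with normalization", {
  sl <- c(chr1 = 50000L)
  bins <- genome_bins(sl, 200)
  set.seed(11)
  reads <- GRanges("chr1", IRanges(sample(100:49000, 500), width = 50),
                   strand = sample(c("+", "-"), 500, TRUE), seqlengths = sl)
  ext <- extend_reads(reads, 200, "treatment")
  ext <- normalize_library(ext, 1e4)
  v <- bin_coverage(ext, bins)
  expect_equal(sum(v * width(bins)), sum(ext$weight * width(ext)))

  # normalize-then-bin equals bin-then-scale (linearity)
  raw <- bin_coverage(extend_reads(reads, 200, "treatment"), bins)
  expect_equal(as.numeric(v), as.numeric(raw) * (1e4 / 500), tolerance = 1e-12)
})

test_that("blacklist filtering removes any bin with at least 1 bp overlap", {
  sl <- c(chr1 = 2000L)
  bins <- genome_bins(sl, 200)
  vals <- matrix(seq_len(20), 10, 2)
  samples <- data.frame(filepath = c("c", "t"), condition = c("WCE", "K4"),
                        is_control = c(TRUE, FALSE), replicate = c(1, 1))
  tracks <- binned_tracks(bins, vals, samples)

  same <- apply_blacklist(tracks, NULL)
  expect_equal(same$values, tracks$values)

  # blacklist covering bins 3-5 exactly
  bl <- GRanges("chr1", IRanges(401, 1000))
  out <- apply_blacklist(tracks, bl)
  expect_equal(nrow(out$values), 7L)
  expect_equal(attr(out, "removed_bins"), 3:5)
  expect_equal(out$values[, 1], vals[-(3:5), 1])

  # a single-bp overlap removes the bin
  bl1 <- GRanges("chr1", IRanges(400, 400))
  out1 <- apply_blacklist(tracks, bl1)
  expect_equal(attr(out1, "removed_bins"), 2L)
})

test_that("bedGraph round-trip preserves values to 6 significant digits", {
  sl <- c(chr1 = 2000L)
  bins <- genome_bins(sl, 200)
  set.seed(3)
  vals <- runif(10, 0, 7)
  f <- tempfile(fileext = ".bedGraph")
  write_bedgraph(bins, vals, f)
  back <- read_bedgraph(f)
  expect_equal(start(back) - 1L, seq(0, 1800, by = 200))
  expect_equal(back$score, vals, tolerance = 1e-6)
})

test_that("fragment length is recovered by strand cross-correlation", {
  set.seed(19)
  centers <- sort(sample(5000:195000, 4000, replace = TRUE))
  reads <- make_stranded_reads(centers, fraglen = 200, chrom_len = 2e5L)
  est <- estimate_fragment_length(reads)
  expect_lt(abs(est - 200), 25)

  plus_only <- reads[strand(reads) == "+"]
  expect_error(estimate_fragment_length(plus_only), "both strands")
})

test_that("control fragment length is the median of treatment estimates", {
  set.seed(23)
  mk <- function(fl) make_stranded_reads(
    sort(sample(5000:195000, 3000, replace = TRUE)), fl, chrom_len = 2e5L)
  sheet <- parse_sample_sheet(data.frame(
    filepath = c("c.bam", "a.bam", "b.bam"),
    condition = c("WCE", "markA", "markB"),
    is_control = c(TRUE, FALSE, FALSE), replicate = c(1, 1, 1)))
  # deterministic spikes: exact fragment lengths 180 and 220
  fl <- estimate_fragment_lengths(list(mk(200), mk(180), mk(220)), sheet)
  expect_equal(unname(fl["WCE"]), unname(median(fl[c("markA", "markB")])))
  expect_lt(abs(fl[["markA"]] - 180), 25)
  expect_lt(abs(fl[["markB"]] - 220), 25)
})

test_that("BAM reading honors QC flags and preprocessing yields binned tracks", {
  chrom_lens <- c(chrT = 50000L)
  set.seed(31)
  n <- 400
  centers <- sample(2000:48000, n, replace = TRUE)
  pos_strand <- seq_len(n) %% 2 == 0
  reads <- data.frame(
    qname = sprintf("r%04d", seq_len(n)),
    flag = ifelse(pos_strand, 0L, 16L),
    chrom = "chrT",
    pos = ifelse(pos_strand, centers - 100L, centers + 100L - 50L + 1L),
    seq_len = 50L)
  # one duplicate and one QC-fail read must be filtered out
  bad <- data.frame(qname = c("dup", "qcfail"), flag = c(1024L, 512L),
                    chrom = "chrT", pos = c(1000L, 1200L), seq_len = 50L)
  bam_t <- make_test_bam(rbind(reads, bad), chrom_lens)
  got <- read_alignments(bam_t)
  expect_equal(length(got), n)
  expect_equal(sum(strand(got) == "+"), sum(pos_strand))

  bam_c <- make_test_bam(reads[sample(n, 200), ], chrom_lens)
  sheet <- parse_sample_sheet(data.frame(
    filepath = c(bam_c, bam_t), condition = c("WCE", "mark"),
    is_control = c(TRUE, FALSE), replicate = c(1, 1)))
  tracks <- preprocess_samples(sheet, bin_width = 200)
  expect_s3_class(tracks, "binned_tracks")
  expect_equal(dim(tracks$values), c(250L, 2L))
  expect_true(all(tracks$values >= 0))
  # per-sample weighted mass: 25M reads x fragment length / genome,
  # up to chromosome-edge clipping
  expect_equal(sum(tracks$values[, 2] * width(tracks$bins)),
               25e6 * tracks$fragment_lengths[["mark"]], tolerance = 0.01)
})
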