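# Coverage binning, library-size correction, the ratio statistic and CNV
# segmentation.

test_that("bedGraph intervals are aggregated by overlap length", {
  bg <- tempfile(fileext = ".bedGraph")
  writeLines(c("s1\t0\t500\t4", "s1\t500\t1500\t8"), bg)
  trk <- binCoverage(bg, c(s1 = 2000), binSize = 1000)
  # bin 1: 500*4 + 500*8 = 6000; bin 2: 500*8 = 4000
  expect_equal(binCounts(trk), c(6000, 4000))

  uniform <- tempfile(fileext = ".bedGraph")
  writeLines("s1\t0\t3000\t10", uniform)
  expect_equal(binCounts(binCoverage(uniform, c(s1 = 3000), 1000)),
               rep(10000, 3))

  bad <- tempfile(fileext = ".bedGraph")
  writeLines("unknown\t0\t100\t1", bad)
  expect_error(binCoverage(bad, c(s1 = 3000), 1000), "unknown")
})

test_that("the last partial bin keeps its true width", {
  bg <- tempfile(fileext = ".bedGraph")
  writeLines("s1\t0\t2500\t2", bg)
  trk <- binCoverage(bg, c(s1 = 2500), binSize = 1000)
  expect_equal(GenomicRanges::width(binRanges(trk)), c(1000, 1000, 500))
  expect_equal(binCounts(trk), c(2000, 2000, 1000))
})

test_that("BAM per-base depth is summed per bin with MAPQ filtering", {
  sam <- tempfile(fileext = ".sam")
  writeTinySam(sam, scaffold = "s1", scaffoldLen = 3000,
               readStarts = c(101L, 1201L), readLen = 100L,
               mapq = c(60L, 5L))
  bam <- Rsamtools::asBam(sam, overwrite = TRUE)
  trk <- binCoverage(bam, c(s1 = 3000), binSize = 1000, format = "bam")
  expect_equal(binCounts(trk), c(100, 100, 0))
  high <- binCoverage(bam, c(s1 = 3000), binSize = 1000, minMapq = 30,
                      format = "bam")
  expect_equal(binCounts(high), c(100, 0, 0))
})

test_that("library scale: identities and the doubling case", {
  a <- makeTrack(c(10, 20, 30, 40, 50))
  expect_equal(libraryScale(a, a, mode = "totals"), 1)
  expect_equal(libraryScale(a, a, mode = "median-recenter"), 1)
  doubled <- makeTrack(2 * c(10, 20, 30, 40, 50))
  s <- libraryScale(a, doubled, mode = "totals")
  expect_equal(s, 0.5)
  r <- S4Vectors::mcols(ratioScan(a, doubled, s = s, minCombined = 1))$r
  expect_equal(r, rep(0.5, 5))
})

test_that("scale modes agree when CNVs cover <5% of bins", {
  p <- SimParams(nAutosomes = 5, nZScaffolds = 0, scaffoldLength = 200000L,
                 libraryScaleComparison = 1.7, seed = 21L,
                 cnvSegments = data.frame(scaffold = "scaffold_1",
                                          start = 1, end = 10000,
                                          focal_copies = 2,
                                          comparison_copies = 4))
  sim <- simulateGenome(p)
  m <- simulateCoverage(p, sim$truth, "male")
  f <- simulateCoverage(p, sim$truth, "female")
  sTot <- libraryScale(m, f, "totals")
  sMed <- libraryScale(m, f, "median-recenter")
  expect_equal(sMed / sTot, 1, tolerance = 0.02)
})

test_that("per-bin ratio r = e/(e + s a) with masking of empty bins", {
  focal <- makeTrack(c(10, 10, 0, 2))
  comp <- makeTrack(c(10, 20, 0, 2))
  rs <- ratioScan(focal, comp, s = 1, minCombined = 5)
  mc <- S4Vectors::mcols(rs)
  expect_equal(mc$r[1], 0.5)
  expect_equal(mc$r[2], 1 / 3)
  expect_true(is.na(mc$r[3]) && mc$masked[3])   # 0/0 undefined
  expect_true(is.na(mc$r[4]) && mc$masked[4])   # below minCombined
  expect_true(all(mc$r >= 0 & mc$r <= 1, na.rm = TRUE))
})

test_that("swapping focal and comparison maps r to 1 - r and flips calls", {
  set.seed(33)
  e <- rpois(400, 30000)
  a <- rpois(400, 30000)
  a[101:150] <- rpois(50, 60000)   # comparison gain
  e[301:340] <- rpois(40, 60000)   # comparison loss after the swap
  fw <- ratioScan(makeTrack(e), makeTrack(a), s = 1)
  bw <- ratioScan(makeTrack(a), makeTrack(e), s = 1)
  expect_equal(S4Vectors::mcols(fw)$r, 1 - S4Vectors::mcols(bw)$r)
  cf <- callCnv(fw); cb <- callCnv(bw)
  expect_equal(GenomicRanges::start(cf), GenomicRanges::start(cb))
  swap <- c(comparison_gain = "comparison_loss",
            comparison_loss = "comparison_gain")
  expect_equal(unname(swap[S4Vectors::mcols(cf)$direction]),
               S4Vectors::mcols(cb)$direction)
})

test_that("identical tracks give r = 0.5 everywhere and no calls", {
  set.seed(12)
  t1 <- makeTrack(rpois(500, 30000))
  rs <- ratioScan(t1, t1, s = 1)
  expect_true(all(S4Vectors::mcols(rs)$r == 0.5))
  expect_length(callCnv(rs), 0L)
})

test_that("threshold validation and gap tolerance in segmentation", {
  expect_error(callCnv(GenomicRanges::GRanges(), lowThr = 0.6),
               "thresholds")
  r <- rep(0.5, 30)
  r[5:14] <- 0.33
  r[10] <- 0.5              # one-bin interruption, within maxGapBins = 2
  rs <- makeTrack(rep(100, 30))
  gr <- GenomicRanges::granges(binRanges(rs))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    e = rep(100, 30), aCorrected = rep(100, 30), r = r,
    masked = rep(FALSE, 30))
  calls <- callCnv(gr, minBins = 5, maxGapBins = 2)
  expect_length(calls, 1L)
  expect_equal(S4Vectors::mcols(calls)$nBins, 9L)
  # zero gap tolerance splits the run into 5- and 4-bin halves
  expect_length(callCnv(gr, minBins = 6, maxGapBins = 0), 0L)
  expect_length(callCnv(gr, minBins = 4, maxGapBins = 0), 2L)
})

test_that("a planted comparison-doubled segment is recovered precisely", {
  p <- SimParams(nAutosomes = 4, nZScaffolds = 0, scaffoldLength = 500000L,
                 seed = 17L,
                 cnvSegments = data.frame(scaffold = "scaffold_2",
                                          start = 150001, end = 350000,
                                          focal_copies = 2,
                                          comparison_copies = 4))
  sim <- simulateGenome(p)
  m <- simulateCoverage(p, sim$truth, "male")
  f <- simulateCoverage(p, sim$truth, "female")
  rs <- ratioScan(m, f, s = 1)
  calls <- callCnv(rs)
  expect_length(calls, 1L)
  expect_equal(S4Vectors::mcols(calls)$direction, "comparison_gain")
  truthSeg <- cnvSegments(sim$truth)
  expect_lte(abs(GenomicRanges::start(calls) -
                 GenomicRanges::start(truthSeg)), 2000)
  expect_lte(abs(GenomicRanges::end(calls) -
                 GenomicRanges::end(truthSeg)), 2000)
  expect_equal(S4Vectors::mcols(calls)$fold, 2, tolerance = 0.05)
})

test_that("CNV calls export as BED and TSV", {
  gr <- GenomicRanges::GRanges("s1", IRanges::IRanges(1001, 5000),
                               meanR = 1 / 3, nBins = 4L,
                               direction = "comparison_gain", fold = 2)
  bed <- tempfile(fileext = ".bed"); tsv <- tempfile(fileext = ".tsv")
  writeCnvCalls(gr, bedPath = bed, tsvPath = tsv)
  b <- read.table(bed, sep = "\t")
  expect_equal(b$V2, 1000); expect_equal(b$V3, 5000)
  expect_equal(b$V4, "comparison_gain"); expect_equal(b$V5, 333)
  t <- read.table(tsv, sep = "\t", header = TRUE)
  expect_equal(t$fold, 2)
})
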