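# Synthetic-data generator: parameter validation, truth bookkeeping and the
# statistical structure of simulated coverage.

test_that("SimParams validates its invariants", {
  expect_error(SimParams(scaffoldLength = 1500, binSize = 1000),
               "multiple of binSize")
  expect_error(SimParams(depthPerCopy = 0), "depthPerCopy")
  expect_error(SimParams(dispersion = -1), "dispersion")
  overlapping <- data.frame(
    scaffold = "scaffold_1", start = c(1, 500), end = c(1000, 1500),
    focal_copies = 2, comparison_copies = 4)
  expect_error(
    SimParams(nAutosomes = 1, scaffoldLength = 10000,
              cnvSegments = overlapping),
    "overlap")
  expect_error(
    SimParams(nAutosomes = 1, scaffoldLength = 5000,
              cnvSegments = data.frame(scaffold = "scaffold_1",
                                       start = 4000, end = 9000,
                                       focal_copies = 2,
                                       comparison_copies = 4)),
    "bounds")
})

test_that("simulateGenome labels Z scaffolds and expected ratios", {
  p <- SimParams(nAutosomes = 2, nZScaffolds = 1, scaffoldLength = 20000,
                 cnvSegments = data.frame(scaffold = "scaffold_2",
                                          start = 1, end = 5000,
                                          focal_copies = 2,
                                          comparison_copies = 4))
  sim <- simulateGenome(p)
  expect_length(zScaffolds(sim$truth), 1L)
  expect_equal(S4Vectors::mcols(cnvSegments(sim$truth))$expectedRatio,
               2 / (2 + 4))
  expect_equal(sort(names(sim$sequences)),
               sort(names(scaffoldLengths(sim$truth))))
  expect_equal(unname(Biostrings::width(sim$sequences)), rep(20000L, 3))
})

test_that("expected ratios are normalized to [0, 1] for random copy pairs", {
  set.seed(42)
  for (i in 1:100) {
    fc <- sample(1:6, 1); cc <- sample(1:6, 1)
    p <- SimParams(nAutosomes = 1, scaffoldLength = 10000,
                   cnvSegments = data.frame(scaffold = "scaffold_1",
                                            start = 1, end = 3000,
                                            focal_copies = fc,
                                            comparison_copies = cc))
    er <- S4Vectors::mcols(cnvSegments(simulateGenome(p)$truth))$expectedRatio
    expect_true(er >= 0 && er <= 1)
  }
})

test_that("fixed seed gives bit-identical genomes and tracks", {
  a <- smallSim(seed = 7L)
  b <- smallSim(seed = 7L)
  expect_identical(as.character(a$sequences), as.character(b$sequences))
  expect_identical(binCounts(a$male), binCounts(b$male))
  expect_identical(binCounts(a$female), binCounts(b$female))
  c <- smallSim(seed = 8L)
  expect_false(identical(binCounts(a$male), binCounts(c$male)))
})

test_that("neutral autosomal male bins average phi * 2 * binSize", {
  p <- SimParams(nAutosomes = 10, nZScaffolds = 0,
                 scaffoldLength = 1000000L, seed = 3L)
  sim <- simulateGenome(p)
  m <- simulateCoverage(p, sim$truth, "male")
  mu <- 15 * 2 * 1000
  expect_equal(mean(binCounts(m)), mu, tolerance = 0.02)
})

test_that("female Z coverage is half the male Z coverage", {
  s <- smallSim(seed = 2L, nAutosomes = 1, nZScaffolds = 1,
                scaffoldLength = 500000L)
  onZ <- as.character(GenomicRanges::seqnames(binRanges(s$male))) %in%
    zScaffolds(s$truth)
  ratio <- mean(binCounts(s$female)[onZ]) / mean(binCounts(s$male)[onZ])
  expect_equal(ratio, 0.5, tolerance = 0.02)
})

test_that("dispersion 0 gives Poisson-like variance and NB inflates it", {
  p <- SimParams(nAutosomes = 10, nZScaffolds = 0,
                 scaffoldLength = 1000000L, seed = 5L)
  sim <- simulateGenome(p)
  cnt <- binCounts(simulateCoverage(p, sim$truth, "male"))
  expect_equal(var(cnt) / mean(cnt), 1, tolerance = 0.05)

  pd <- SimParams(nAutosomes = 2, nZScaffolds = 0,
                  scaffoldLength = 1000000L, dispersion = 0.001, seed = 5L)
  simd <- simulateGenome(pd)
  cntd <- binCounts(simulateCoverage(pd, simd$truth, "male"))
  mu <- mean(cntd)
  # var = mu (1 + dispersion * mu): 0.001 * 30000 = 31-fold inflation
  expect_gt(var(cntd) / mu, 10)
})

test_that("library scale moves raw counts but not truth ratios", {
  mk <- function(scale) {
    p <- SimParams(nAutosomes = 2, scaffoldLength = 100000L,
                   libraryScaleComparison = scale, seed = 11L,
                   cnvSegments = data.frame(scaffold = "scaffold_1",
                                            start = 1, end = 20000,
                                            focal_copies = 2,
                                            comparison_copies = 4))
    sim <- simulateGenome(p)
    list(truth = sim$truth,
         female = simulateCoverage(p, sim$truth, "female"))
  }
  a <- mk(1); b <- mk(2)
  expect_equal(mean(binCounts(b$female)) / mean(binCounts(a$female)), 2,
               tolerance = 0.02)
  expect_identical(
    S4Vectors::mcols(cnvSegments(a$truth))$expectedRatio,
    S4Vectors::mcols(cnvSegments(b$truth))$expectedRatio)
})

test_that("unknown sex label is rejected", {
  s <- smallSim(seed = 1L, nAutosomes = 1, nZScaffolds = 0,
                scaffoldLength = 10000L)
  expect_error(simulateCoverage(s$params, s$truth, "hermaphrodite"))
})

test_that("simulateExons honours class counts and GC constraints", {
  ex <- simulateExons(c(15, 16, 9, 14, 3), exonLength = 100L, seed = 9L)
  expect_length(ex, 57L)
  mc <- S4Vectors::mcols(ex)
  expect_equal(as.integer(table(mc$gcClass)), c(15L, 16L, 9L, 14L, 3L))
  # realized GC must fall inside each assigned class
  expect_true(all(mc$gcPct[mc$gcClass == ">=70"] >= 70))
  expect_true(all(mc$gcPct[mc$gcClass == "<40"] < 40))
  recls <- gcClassOf(gcPercent(ex))
  expect_equal(as.character(recls), as.character(mc$gcClass))
  # a 1-bp exon cannot land strictly inside 60-69%
  expect_error(simulateExons(c("60-69" = 1L), exonLength = 1L),
               "no achievable GC")
})

test_that("simulateQpcr inverts the curve exactly at zero noise", {
  crv <- perfectCurve()
  eq <- simulateQpcr(1, crv, noiseSd = 0, replicates = 2)
  expect_equal(eq$ct[eq$assay_id == "target"],
               eq$ct[eq$assay_id == "control"])
  # a comparison-side doubling is exactly one cycle at 100% efficiency
  twoX <- simulateQpcr(2, crv, noiseSd = 0, replicates = 2)
  dCt <- mean(twoX$ct[twoX$assay_id == "target"]) -
    mean(twoX$ct[twoX$assay_id == "control"])
  expect_equal(dCt, -1, tolerance = 1e-12)
  expect_error(simulateQpcr(0, crv), "positive")
  expect_error(simulateQpcr(-2, crv), "positive")
})

test_that("bedGraph and BED writers round-trip coordinates", {
  s <- smallSim(seed = 4L, nAutosomes = 1, nZScaffolds = 1,
                scaffoldLength = 10000L,
                cnvSegments = data.frame(scaffold = "scaffold_1",
                                         start = 2001, end = 4000,
                                         focal_copies = 2,
                                         comparison_copies = 4))
  bg <- tempfile(fileext = ".bedGraph")
  writeCoverageBedGraph(s$male, bg)
  reread <- binCoverage(bg, scaffoldLengths(s$truth), binSize = 1000)
  expect_equal(binCounts(reread), binCounts(s$male))

  cnvBed <- tempfile(fileext = ".bed"); zBed <- tempfile(fileext = ".bed")
  writeTruthBed(s$truth, cnvPath = cnvBed, zPath = zBed)
  cnv <- read.table(cnvBed, sep = "\t")
  expect_equal(cnv$V2, 2000); expect_equal(cnv$V3, 4000)
  z <- read.table(zBed, sep = "\t")
  expect_equal(z$V1, "scaffoldZ_1"); expect_equal(z$V3, 10000)
})
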