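# Shared fixtures: all built in code at test time.

# Brute-force Nxx/Lxx oracle: scan every descending-cumulative prefix and
# return the first whose sum reaches frac of the reference length.
bruteNxx <- function(lengths, frac, ref = sum(as.numeric(lengths))) {
  l <- sort(lengths, decreasing = TRUE)
  running <- 0
  for (k in seq_along(l)) {
    running <- running + as.numeric(l[k])
    if (running >= frac * ref) return(list(n = l[k], l = k))
  }
  NULL
}

# Build a CoverageTrack directly from per-bin counts on one or more
# scaffolds of equal bin count, bypassing the simulator.
makeTrack <- function(counts, binSize = 1000L, sampleId = "s",
                      scaffold = "s1") {
  if (!is.list(counts)) counts <- setNames(list(counts), scaffold)
  df <- do.call(rbind, lapply(names(counts), function(sq)
    data.frame(sq = sq,
               start = seq(1L, by = binSize, length.out = length(counts[[sq]])),
               count = as.numeric(counts[[sq]]))))
  bins <- GenomicRanges::GRanges(
    df$sq, IRanges::IRanges(df$start, width = binSize), count = df$count)
  new("CoverageTrack", sampleId = sampleId, binSize = as.integer(binSize),
      bins = bins)
}

# Small two-sample simulation used by several suites.
smallSim <- function(seed = 1L, nAutosomes = 3L, nZScaffolds = 1L,
                     scaffoldLength = 100000L, ...) {
  p <- SimParams(nAutosomes = nAutosomes, nZScaffolds = nZScaffolds,
                 scaffoldLength = scaffoldLength, seed = seed, ...)
  sim <- simulateGenome(p)
  list(params = p, truth = sim$truth, sequences = sim$sequences,
       male = simulateCoverage(p, sim$truth, "male"),
       female = simulateCoverage(p, sim$truth, "female"))
}

# A tiny coordinate-sorted SAM with reads fully inside known bins.
writeTinySam <- function(path, scaffold = "s1", scaffoldLen = 3000L,
                         readStarts = 101L, readLen = 100L, mapq = 60L) {
  seq <- paste(rep("A", readLen), collapse = "")
  lines <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", scaffold, scaffoldLen),
    vapply(seq_along(readStarts), function(i)
      sprintf("r%d\t0\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t*",
              i, scaffold, readStarts[i], mapq[min(i, length(mapq))],
              readLen, seq),
      character(1)))
  writeLines(lines, path)
  path
}
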