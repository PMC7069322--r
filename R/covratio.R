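# Two-sample binned coverage-ratio statistic and CNV segmentation.
#
# The per-bin statistic is r = e / (e + s * a), where e and a are binned
# coverages of the focal and comparison samples and s corrects for library
# size. With equal copy number and corrected libraries r is centred on 0.5;
# deviations flag copy-number differences between the two individuals
# (e.g. a comparison-side doubling pulls r towards 1/3).

#' Bin per-base coverage into a CoverageTrack
#'
#' Sums per-base depth per fixed-width bin, either from a bedGraph track
#' (values aggregated by overlap length) or from an indexed BAM file
#' (per-base pileup depth, optionally MAPQ-filtered). The last bin of each
#' scaffold keeps its true (possibly shorter) width.
#'
#' @param x path to a bedGraph file, a `GRanges` with a numeric `score`
#'   column, or a path to an indexed BAM file.
#' @param seqlengths named vector of scaffold lengths, e.g. from a FASTA
#'   index (`.fai`) via [readFaidx()], or a
#'   [GenomeInfoDb::Seqinfo] object.
#' @param binSize bin width in bp.
#' @param sampleId sample label.
#' @param minMapq minimum mapping quality (BAM input only).
#' @param format force `"bedGraph"` or `"bam"`; by default inferred from
#'   the file extension.
#' @return A [CoverageTrack-class].
#' @examples
#' bg <- tempfile(fileext = ".bedGraph")
#' writeLines(c("s1\t0\t500\t4", "s1\t500\t1500\t8"), bg)
#' binCounts(binCoverage(bg, c(s1 = 2000), binSize = 1000))  # 6000 4000
#' @export
binCoverage <- function(x, seqlengths, binSize = 1000L, sampleId = "sample",
                        minMapq = 0L, format = NULL) {
  if (binSize < 1L) stop("binSize must be >= 1")
  if (is(seqlengths, "Seqinfo"))
    seqlengths <- setNames(GenomeInfoDb::seqlengths(seqlengths),
                           GenomeInfoDb::seqnames(seqlengths))
  if (is.null(names(seqlengths)))
    stop("seqlengths must be named by scaffold")
  bins <- tileGenome(seqlengths, tilewidth = as.integer(binSize),
                     cut.last.tile.in.chrom = TRUE)

  if (is.character(x)) {
    if (is.null(format))
      format <- if (grepl("\\.bam$", x, ignore.case = TRUE)) "bam" else
        "bedGraph"
    if (format == "bam")
      return(.binBam(x, bins, seqlengths, binSize, sampleId, minMapq))
    x <- rtracklayer::import(x, format = "bedGraph")
  }
  stopifnot(is(x, "GRanges"))
  bad <- setdiff(unique(as.character(seqnames(x))), names(seqlengths))
  if (length(bad))
    stop("scaffolds absent from seqlengths: ", paste(bad, collapse = ", "))
  score <- mcols(x)$score
  if (is.null(score)) stop("interval input needs a numeric 'score' column")

  counts <- numeric(length(bins))
  covRle <- GenomicRanges::coverage(
    GRanges(seqnames(x), ranges(x),
            seqinfo = Seqinfo(names(seqlengths),
                              unname(as.integer(seqlengths)))),
    weight = as.numeric(score))
  binsBySeq <- split(seq_along(bins), as.character(seqnames(bins)))
  for (sq in names(binsBySeq)) {
    idx <- binsBySeq[[sq]]
    v <- Views(covRle[[sq]], ranges(bins)[idx])
    counts[idx] <- IRanges::viewSums(v)
  }
  mcols(bins)$count <- counts
  new("CoverageTrack", sampleId = sampleId,
      binSize = as.integer(binSize), bins = bins)
}

.binBam <- function(path, bins, seqlengths, binSize, sampleId, minMapq) {
  bamSeqs <- names(Rsamtools::scanBamHeader(path)[[1]]$targets)
  bad <- setdiff(names(seqlengths), bamSeqs)
  if (length(bad))
    stop("scaffolds absent from BAM header: ", paste(bad, collapse = ", "))
  pp <- Rsamtools::PileupParam(max_depth = .Machine$integer.max %/% 2L,
                               min_mapq = as.integer(minMapq),
                               min_base_quality = 0L,
                               min_nucleotide_depth = 1L,
                               distinguish_strands = FALSE,
                               distinguish_nucleotides = FALSE)
  sbp <- Rsamtools::ScanBamParam(
    which = GRanges(names(seqlengths),
                    IRanges(1L, unname(as.integer(seqlengths)))))
  p <- Rsamtools::pileup(path, scanBamParam = sbp, pileupParam = pp)
  counts <- numeric(length(bins))
  if (nrow(p) > 0L) {
    pos <- GRanges(p$seqnames, IRanges(p$pos, width = 1L))
    hits <- findOverlaps(pos, bins)
    add <- tapply(p$count[S4Vectors::queryHits(hits)],
                  S4Vectors::subjectHits(hits), sum)
    counts[as.integer(names(add))] <- as.numeric(add)
  }
  mcols(bins)$count <- counts
  new("CoverageTrack", sampleId = sampleId,
      binSize = as.integer(binSize), bins = bins)
}

#' Read a FASTA index into named scaffold lengths
#'
#' @param path a `.fai` file (as produced by `samtools faidx`).
#' @return Named integer vector of scaffold lengths.
#' @export
readFaidx <- function(path) {
  fai <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (anyDuplicated(fai[[1]])) stop("duplicate scaffold names in ", path)
  setNames(as.integer(fai[[2]]), fai[[1]])
}

.checkComparable <- function(focal, comparison) {
  stopifnot(is(focal, "CoverageTrack"), is(comparison, "CoverageTrack"))
  if (focal@binSize != comparison@binSize)
    stop("tracks use different bin sizes")
  gf <- granges(binRanges(focal)); gc <- granges(binRanges(comparison))
  if (length(gf) != length(gc) || !identical(as.character(seqnames(gf)),
                                             as.character(seqnames(gc))) ||
      !identical(start(gf), start(gc)) || !identical(end(gf), end(gc)))
    stop("tracks are not binned over the same scaffolds/bins")
}

#' Estimate the library-size scale factor s
#'
#' `s` multiplies the comparison counts so the two libraries become
#' comparable: corrected comparison coverage is `s * a`. Mode `"totals"`
#' uses the ratio of summed coverages, `s = total_focal /
#' total_comparison`. The default `"median-recenter"` chooses s so the
#' genome-wide median of the per-bin ratio e/(e + s*a) equals 0.5, i.e.
#' `s = median(e/a)` over informative bins — robust to CNVs and Z-linked
#' scaffolds that distort totals.
#'
#' @param focal,comparison [CoverageTrack-class] objects on identical bins.
#' @param mode `"median-recenter"` (default) or `"totals"`.
#' @return The scalar s.
#' @examples
#' p <- SimParams(nAutosomes = 2, scaffoldLength = 50000, nZScaffolds = 0)
#' sim <- simulateGenome(p)
#' m <- simulateCoverage(p, sim$truth, "male")
#' f <- simulateCoverage(p, sim$truth, "female")
#' libraryScale(m, f)
#' @export
libraryScale <- function(focal, comparison,
                         mode = c("median-recenter", "totals")) {
  mode <- match.arg(mode)
  .checkComparable(focal, comparison)
  e <- binCounts(focal); a <- binCounts(comparison)
  if (mode == "totals") {
    if (sum(a) == 0 || sum(e) == 0) stop("zero total coverage")
    return(sum(e) / sum(a))
  }
  ok <- a > 0 & e > 0
  if (!any(ok)) stop("no informative bins for median-recentering")
  median(e[ok] / a[ok])
}

#' Per-bin two-sample coverage ratios
#'
#' Computes r = e / (e + s*a) for every bin. Bins whose combined corrected
#' coverage e + s*a falls below `minCombined` are masked (`r = NA`): the
#' ratio is undefined at zero coverage and unstable just above it.
#'
#' @param focal,comparison [CoverageTrack-class] objects on identical bins.
#' @param s library-size scale from [libraryScale()] (or 1 for equal
#'   libraries).
#' @param minCombined minimum e + s*a for a bin to stay unmasked.
#' @return A `GRanges` (one range per bin) with metadata columns `e`,
#'   `aCorrected`, `r` and `masked`.
#' @examples
#' p <- SimParams(nAutosomes = 1, nZScaffolds = 0, scaffoldLength = 20000)
#' sim <- simulateGenome(p)
#' m <- simulateCoverage(p, sim$truth, "male")
#' f <- simulateCoverage(p, sim$truth, "female")
#' head(ratioScan(m, f, s = 1))
#' @export
ratioScan <- function(focal, comparison, s = NULL, minCombined = 10) {
  .checkComparable(focal, comparison)
  if (is.null(s)) s <- libraryScale(focal, comparison)
  if (!is.finite(s) || s <= 0) stop("s must be positive")
  out <- granges(binRanges(focal))
  e <- binCounts(focal)
  ac <- s * binCounts(comparison)
  denom <- e + ac
  masked <- denom < minCombined
  r <- ifelse(denom > 0, e / denom, NA_real_)
  r[masked] <- NA_real_
  mcols(out) <- DataFrame(e = e, aCorrected = ac, r = r, masked = masked)
  metadata(out) <- list(s = s, minCombined = minCombined,
                        focal = sampleId(focal),
                        comparison = sampleId(comparison))
  out
}

# split qualifying bin indices into runs allowing gaps of <= maxGap bins
.runsWithGaps <- function(idx, maxGap) {
  if (length(idx) == 0L) return(list())
  grp <- cumsum(c(0L, as.integer(diff(idx) - 1L > maxGap)))
  unname(split(idx, grp))
}

#' Call CNV segments from bin ratios
#'
#' Finds maximal runs of unmasked bins with r <= `lowThr` (direction
#' `comparison_gain`: the comparison sample carries extra copies) or r >=
#' `highThr` (`comparison_loss`), allowing interruptions of up to
#' `maxGapBins` non-qualifying bins, and drops runs with fewer than
#' `minBins` qualifying bins. Each segment reports the mean ratio over its
#' qualifying bins and the implied comparison:focal copy fold
#' `(1 - mean_r) / mean_r` (2.0 at r = 1/3).
#'
#' @param ratios the `GRanges` from [ratioScan()].
#' @param lowThr,highThr ratio thresholds, 0 < lowThr < 0.5 < highThr < 1.
#' @param minBins minimum qualifying bins per segment.
#' @param maxGapBins maximum run interruption, in bins.
#' @return A `GRanges` of segments with metadata columns `meanR`, `nBins`,
#'   `direction` and `fold`; zero-length when nothing deviates.
#' @export
callCnv <- function(ratios, lowThr = 0.40, highThr = 0.60,
                    minBins = 5L, maxGapBins = 2L) {
  stopifnot(is(ratios, "GRanges"))
  if (!(lowThr > 0 && lowThr < 0.5 && highThr > 0.5 && highThr < 1))
    stop("thresholds must satisfy 0 < lowThr < 0.5 < highThr < 1")
  r <- mcols(ratios)$r
  segs <- list()
  bySeq <- split(seq_along(ratios), as.character(seqnames(ratios)))
  for (sq in names(bySeq)) {
    idx <- bySeq[[sq]][order(start(ratios)[bySeq[[sq]]])]
    for (dir in c("comparison_gain", "comparison_loss")) {
      qual <- if (dir == "comparison_gain") {
        idx[!is.na(r[idx]) & r[idx] <= lowThr]
      } else {
        idx[!is.na(r[idx]) & r[idx] >= highThr]
      }
      # positions within idx, so gaps are counted in bins not coordinates
      posOf <- match(qual, idx)
      for (run in .runsWithGaps(posOf, maxGapBins)) {
        if (length(run) < minBins) next
        bi <- idx[run]
        meanR <- mean(r[bi])
        segs[[length(segs) + 1L]] <- data.frame(
          seqnames = sq, start = min(start(ratios)[bi]),
          end = max(end(ratios)[bi]), meanR = meanR,
          nBins = length(bi), direction = dir,
          fold = (1 - meanR) / meanR, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(segs) == 0L) {
    g <- GRanges()
    mcols(g) <- DataFrame(meanR = numeric(0), nBins = integer(0),
                          direction = character(0), fold = numeric(0))
    return(g)
  }
  df <- do.call(rbind, segs)
  out <- GRanges(df$seqnames, IRanges(df$start, df$end),
                 meanR = df$meanR, nBins = df$nBins,
                 direction = df$direction, fold = df$fold)
  sort(out)
}

#' Write CNV calls as BED plus a detail TSV
#'
#' BED name is the call direction and score is `round(1000 * meanR)`; the
#' TSV adds `mean_r`, `fold` and `n_bins` columns.
#'
#' @param calls segments from [callCnv()].
#' @param bedPath,tsvPath output files (`NULL` skips either).
#' @return Invisibly, the paths written.
#' @export
writeCnvCalls <- function(calls, bedPath = NULL, tsvPath = NULL) {
  mc <- mcols(calls)
  written <- character(0)
  if (!is.null(bedPath)) {
    df <- .grToBedDf(calls, name = as.character(mc$direction),
                     score = round(1000 * mc$meanR))
    write.table(df, bedPath, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    written <- c(written, bedPath)
  }
  if (!is.null(tsvPath)) {
    df <- data.frame(scaffold = as.character(seqnames(calls)),
                     start = start(calls) - 1L, end = end(calls),
                     direction = as.character(mc$direction),
                     mean_r = mc$meanR, fold = mc$fold, n_bins = mc$nBins)
    write.table(df, tsvPath, sep = "\t", quote = FALSE, row.names = FALSE)
    written <- c(written, tsvPath)
  }
  invisible(written)
}
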