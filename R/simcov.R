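# Synthetic two-sample coverage data with known truth.
#
# The generator emulates the study design the ratio scan assumes: a focal
# male (ZZ) and a comparison female (ZW) individual sequenced on libraries of
# possibly unequal size, mapped to one multi-scaffold assembly, with
# copy-number segments planted on known coordinates.

.simSeedOffsets <- c(genome = 0L, male = 11L, female = 23L, exons = 37L,
                     qpcr = 53L)

#' Construct simulation parameters
#'
#' @param nAutosomes number of autosomal scaffolds.
#' @param nZScaffolds number of Z-linked scaffolds.
#' @param scaffoldLength scaffold length in bp (multiple of `binSize`).
#' @param binSize bin width in bp.
#' @param depthPerCopy mean per-base depth contributed by one haploid copy;
#'   the default 15 puts diploid autosomal depth at ~30x, the order of a
#'   typical short-read whole-genome run.
#' @param dispersion non-negative overdispersion; 0 = Poisson, otherwise
#'   negative binomial with variance mu * (1 + dispersion * mu).
#' @param libraryScaleComparison multiplicative library-size factor applied
#'   to the comparison (female) sample.
#' @param cnvSegments planted copy-number segments: a `GRanges` with
#'   metadata columns `focalCopies` and `comparisonCopies`, or a
#'   `data.frame` with columns `scaffold`, `start`, `end` (1-based,
#'   inclusive), `focal_copies`, `comparison_copies`. May be empty.
#' @param gc target genome GC fraction for the simulated sequence.
#' @param seed integer seed; every RNG stream of the simulator derives from
#'   it, so a fixed seed gives bit-identical genomes, tracks and tables.
#'
#' @return A validated [SimParams-class] object.
#' @examples
#' SimParams(nAutosomes = 2, nZScaffolds = 1, scaffoldLength = 50000)
#' @export
SimParams <- function(nAutosomes = 5L, nZScaffolds = 1L,
                      scaffoldLength = 1000000L, binSize = 1000L,
                      depthPerCopy = 15, dispersion = 0,
                      libraryScaleComparison = 1,
                      cnvSegments = GRanges(), gc = 0.42, seed = 1L) {
  if (is.data.frame(cnvSegments)) {
    need <- c("scaffold", "start", "end", "focal_copies", "comparison_copies")
    if (!all(need %in% names(cnvSegments)))
      stop("cnvSegments data.frame needs columns: ",
           paste(need, collapse = ", "))
    cnvSegments <- GRanges(
      seqnames = cnvSegments$scaffold,
      ranges = IRanges(cnvSegments$start, cnvSegments$end),
      focalCopies = as.integer(cnvSegments$focal_copies),
      comparisonCopies = as.integer(cnvSegments$comparison_copies)
    )
  }
  new("SimParams",
      nAutosomes = as.integer(nAutosomes),
      nZScaffolds = as.integer(nZScaffolds),
      scaffoldLength = as.integer(scaffoldLength),
      binSize = as.integer(binSize),
      depthPerCopy = as.numeric(depthPerCopy),
      dispersion = as.numeric(dispersion),
      libraryScaleComparison = as.numeric(libraryScaleComparison),
      cnvSegments = cnvSegments,
      gc = as.numeric(gc),
      seed = as.integer(seed))
}

.simScaffoldNames <- function(params) {
  c(if (params@nAutosomes > 0L) paste0("scaffold_", seq_len(params@nAutosomes)),
    if (params@nZScaffolds > 0L) paste0("scaffoldZ_", seq_len(params@nZScaffolds)))
}

#' Simulate a multi-scaffold genome with truth annotations
#'
#' Draws random scaffold sequences at the target GC fraction, labels the
#' Z-linked scaffolds and records the planted copy-number segments together
#' with their expected two-sample coverage ratio
#' r = focal_copies / (focal_copies + comparison_copies).
#'
#' @param params a [SimParams-class] object.
#' @return A list with elements `sequences` (a named
#'   [Biostrings::DNAStringSet]) and `truth` (a [TruthSet-class]).
#' @examples
#' sim <- simulateGenome(SimParams(nAutosomes = 2, nZScaffolds = 1,
#'                                 scaffoldLength = 10000))
#' zScaffolds(sim$truth)
#' @export
simulateGenome <- function(params) {
  stopifnot(is(params, "SimParams"))
  validObject(params)
  set.seed(params@seed + .simSeedOffsets[["genome"]])
  ids <- .simScaffoldNames(params)
  n <- length(ids)
  pr <- c(A = (1 - params@gc) / 2, C = params@gc / 2,
          G = params@gc / 2, T = (1 - params@gc) / 2)
  seqs <- Biostrings::DNAStringSet(vapply(seq_len(n), function(i) {
    paste(sample(names(pr), params@scaffoldLength, replace = TRUE, prob = pr),
          collapse = "")
  }, character(1)))
  names(seqs) <- ids

  lens <- setNames(rep(params@scaffoldLength, n), ids)
  cnv <- params@cnvSegments
  if (length(cnv) > 0L) {
    bad <- setdiff(as.character(seqnames(cnv)), ids)
    if (length(bad))
      stop("cnvSegments reference unknown scaffolds: ",
           paste(bad, collapse = ", "))
    fc <- mcols(cnv)$focalCopies
    cc <- mcols(cnv)$comparisonCopies
    mcols(cnv)$expectedRatio <- fc / (fc + cc)
  }
  truth <- new("TruthSet",
               zScaffolds = grep("^scaffoldZ_", ids, value = TRUE),
               cnvSegments = cnv,
               scaffoldLengths = lens,
               binSize = params@binSize)
  list(sequences = seqs, truth = truth)
}

# Per-bin haploid copy number for one sample. Neutral diploid copy is 2;
# Z-linked scaffolds carry 1 copy in the female; planted segments override
# with overlap-weighted copies so a bin straddling a boundary gets the
# length-weighted mean copy number.
.binCopies <- function(bins, truth, sex, role) {
  copies <- rep(2, length(bins))
  onZ <- as.character(seqnames(bins)) %in% truth@zScaffolds
  if (sex == "female") copies[onZ] <- 1
  cnv <- truth@cnvSegments
  if (length(cnv) > 0L) {
    segCopies <- if (role == "focal") mcols(cnv)$focalCopies else
      mcols(cnv)$comparisonCopies
    hits <- findOverlaps(bins, cnv)
    if (length(hits) > 0L) {
      bi <- S4Vectors::queryHits(hits)
      si <- S4Vectors::subjectHits(hits)
      ov <- width(IRanges::pintersect(ranges(bins)[bi], ranges(cnv)[si]))
      w <- width(bins)[bi]
      # replace the overlapped fraction of the neutral copy number
      delta <- (segCopies[si] - copies[bi]) * ov / w
      add <- tapply(delta, bi, sum)
      idx <- as.integer(names(add))
      copies[idx] <- copies[idx] + as.numeric(add)
    }
  }
  copies
}

#' Simulate a binned coverage track for one individual
#'
#' Per-bin counts are drawn with mean mu = depthPerCopy * c * binWidth *
#' libraryScale, where c is the local haploid copy number: 2 on neutral
#' autosomal bins for both sexes, 1 on Z-linked scaffolds for the female,
#' and the planted copy numbers inside CNV segments. `sex = "male"` is the
#' focal sample (library scale 1, `focalCopies`); `sex = "female"` is the
#' comparison sample (`libraryScaleComparison`, `comparisonCopies`),
#' mirroring a ZZ-male focal / ZW-female comparison study design. With
#' `dispersion = 0` the draw is Poisson, otherwise negative binomial with
#' variance mu * (1 + dispersion * mu).
#'
#' @param params a [SimParams-class] object.
#' @param truth the [TruthSet-class] from [simulateGenome()].
#' @param sex `"male"` (focal) or `"female"` (comparison).
#' @param sampleId sample label; defaults to the sex.
#' @return A [CoverageTrack-class].
#' @examples
#' p <- SimParams(nAutosomes = 1, nZScaffolds = 1, scaffoldLength = 20000)
#' sim <- simulateGenome(p)
#' simulateCoverage(p, sim$truth, "male")
#' @export
simulateCoverage <- function(params, truth, sex = c("male", "female"),
                             sampleId = NULL) {
  stopifnot(is(params, "SimParams"), is(truth, "TruthSet"))
  sex <- match.arg(sex)
  role <- if (sex == "male") "focal" else "comparison"
  scale <- if (role == "comparison") params@libraryScaleComparison else 1
  if (is.null(sampleId)) sampleId <- sex

  set.seed(params@seed + .simSeedOffsets[[sex]])
  bins <- tileGenome(truth@scaffoldLengths, tilewidth = params@binSize,
                     cut.last.tile.in.chrom = TRUE)
  copies <- .binCopies(bins, truth, sex, role)
  mu <- params@depthPerCopy * copies * width(bins) * scale
  counts <- if (params@dispersion == 0) {
    rpois(length(mu), lambda = mu)
  } else {
    rnbinom(length(mu), size = 1 / params@dispersion, mu = mu)
  }
  mcols(bins)$count <- as.numeric(counts)
  new("CoverageTrack", sampleId = sampleId, binSize = params@binSize,
      bins = bins)
}

#' Simulate exon sequences stratified by GC class
#'
#' Generates exon-like sequences whose realized GC content falls inside an
#' assigned GC class, using the five classes >=70, 60-69, 50-59, 40-49 and
#' <40 percent (inclusive lower bounds). The number of G+C bases is fixed to
#' the feasible value nearest the class midpoint, and base order is
#' randomized.
#'
#' @param nPerClass integer vector of exon counts, either named by class
#'   label or unnamed in the order `c(">=70", "60-69", "50-59", "40-49",
#'   "<40")`.
#' @param exonLength exon length in bp (single value or per-class).
#' @param seed integer seed.
#' @return A [Biostrings::DNAStringSet] with metadata columns `gcClass` and
#'   `gcPct`.
#' @examples
#' ex <- simulateExons(c(15, 16, 9, 14, 3), exonLength = 120)
#' table(S4Vectors::mcols(ex)$gcClass)
#' @export
simulateExons <- function(nPerClass, exonLength = 150L, seed = 1L) {
  classes <- gcClassLevels()
  if (is.null(names(nPerClass))) {
    if (length(nPerClass) != length(classes))
      stop("unnamed nPerClass must have one count per class (",
           paste(classes, collapse = ", "), ")")
    names(nPerClass) <- classes
  }
  if (!all(names(nPerClass) %in% classes))
    stop("unknown GC class label(s): ",
         paste(setdiff(names(nPerClass), classes), collapse = ", "))
  exonLength <- as.integer(exonLength)
  if (length(exonLength) == 1L)
    exonLength <- setNames(rep(exonLength, length(nPerClass)),
                           names(nPerClass))
  set.seed(seed + .simSeedOffsets[["exons"]])

  oneExon <- function(class, len) {
    b <- .gcClassBounds(class)
    # feasible G+C base counts whose fraction stays inside the class
    lo <- ceiling(b[1] * len)
    hi <- if (b[2] >= 1) len else ceiling(b[2] * len) - 1L
    if (lo > hi)
      stop("no achievable GC count for class ", class,
           " at length ", len)
    target <- round(mean(c(b[1], min(b[2], 1))) * len)
    nGC <- min(max(target, lo), hi)
    bases <- c(sample(c("G", "C"), nGC, replace = TRUE),
               sample(c("A", "T"), len - nGC, replace = TRUE))
    paste(sample(bases), collapse = "")
  }

  out <- character(0); cls <- character(0)
  for (class in names(nPerClass)) {
    n <- nPerClass[[class]]
    if (n > 0L) {
      out <- c(out, vapply(seq_len(n), function(i)
        oneExon(class, exonLength[[class]]), character(1)))
      cls <- c(cls, rep(class, n))
    }
  }
  seqs <- Biostrings::DNAStringSet(out)
  names(seqs) <- paste0("exon_", seq_along(seqs))
  gc <- 100 * Biostrings::letterFrequency(seqs, "GC", as.prob = TRUE)[, 1]
  mcols(seqs) <- DataFrame(gcClass = factor(cls, levels = classes),
                           gcPct = gc)
  seqs
}

#' Simulate a qPCR Ct table for a target/control assay pair
#'
#' Ct values are produced by evaluating each assay's standard curve at the
#' implied starting copies (control at `controlCopies`, target at
#' `trueRatio * controlCopies`) and adding Gaussian noise of standard
#' deviation `noiseSd` cycles independently per replicate.
#'
#' @param trueRatio true copies of target per copy of control (> 0).
#' @param curve a [StandardCurve-class] used for both assays, or a list with
#'   elements `target` and `control`.
#' @param noiseSd replicate noise in Ct units.
#' @param replicates technical replicates per assay (>= 2).
#' @param nSamples number of simulated individuals.
#' @param controlCopies starting copies of the control region.
#' @param group cohort label copied into the table.
#' @param seed integer seed.
#' @return A `data.frame` with columns `sample_id`, `group`, `assay_id`,
#'   `role` (all `"unknown"`), `replicate` and `ct`, the layout
#'   [quantifyQpcr()] consumes.
#' @examples
#' crv <- perfectCurve()
#' simulateQpcr(2, crv, noiseSd = 0, replicates = 2)
#' @export
simulateQpcr <- function(trueRatio, curve, noiseSd = 0.1, replicates = 2L,
                         nSamples = 1L, controlCopies = 1e4,
                         group = "group1", seed = 1L) {
  if (!is.finite(trueRatio) || trueRatio <= 0)
    stop("trueRatio must be a positive number")
  if (replicates < 2L)
    stop("at least 2 replicates are required")
  if (is(curve, "StandardCurve")) curve <- list(target = curve,
                                                control = curve)
  stopifnot(is(curve$target, "StandardCurve"),
            is(curve$control, "StandardCurve"))
  set.seed(seed + .simSeedOffsets[["qpcr"]])
  rows <- list()
  for (i in seq_len(nSamples)) {
    for (assay in c("target", "control")) {
      copies <- if (assay == "target") trueRatio * controlCopies else
        controlCopies
      crv <- curve[[assay]]
      ct <- crv@slope * log10(copies) + crv@intercept +
        rnorm(replicates, 0, noiseSd)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sprintf("%s_s%02d", group, i), group = group,
        assay_id = assay, role = "unknown",
        replicate = seq_len(replicates), ct = ct)
    }
  }
  do.call(rbind, rows)
}

#' A perfect-efficiency standard curve
#'
#' Convenience constructor for tests and examples: slope
#' -1/log10(2) = -3.3219 (one cycle per doubling, E = 100%) through the
#' given intercept, backed by a noiseless 10-fold dilution series.
#'
#' @param assayId assay label.
#' @param intercept Ct at a single starting copy.
#' @return A [StandardCurve-class].
#' @export
perfectCurve <- function(assayId = "assay", intercept = 40) {
  pts <- data.frame(log10_copies = 2:7)
  pts$ct <- -1 / log10(2) * pts$log10_copies + intercept
  fitStandardCurve(pts, assayId = assayId)
}

# ---- writers -------------------------------------------------------------

.grToBedDf <- function(gr, name = ".", score = 0L) {
  data.frame(chrom = as.character(seqnames(gr)),
             start = start(gr) - 1L, end = end(gr),
             name = name, score = score,
             stringsAsFactors = FALSE)
}

#' Write a coverage track as bedGraph
#'
#' Emits one line per bin (0-based half-open) with the bin's mean per-base
#' depth (`count / binWidth`) as the bedGraph value, so re-binning with
#' [binCoverage()] — which sums per-base depth — recovers the counts and
#' simulated tracks take the same input path as tracks from real
#' alignments.
#'
#' @param track a [CoverageTrack-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeCoverageBedGraph <- function(track, path) {
  stopifnot(is(track, "CoverageTrack"))
  gr <- binRanges(track)
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1L, end = end(gr),
                   value = mcols(gr)$count / width(gr))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write truth annotations as BED
#'
#' @param truth a [TruthSet-class].
#' @param cnvPath BED file for planted CNV segments (name =
#'   focal:comparison copies), or `NULL` to skip.
#' @param zPath BED file of whole Z-linked scaffolds, or `NULL` to skip.
#' @return Invisibly, the paths written.
#' @export
writeTruthBed <- function(truth, cnvPath = NULL, zPath = NULL) {
  stopifnot(is(truth, "TruthSet"))
  written <- character(0)
  if (!is.null(cnvPath)) {
    cnv <- truth@cnvSegments
    df <- .grToBedDf(cnv, name = paste0(mcols(cnv)$focalCopies, ":",
                                        mcols(cnv)$comparisonCopies))
    write.table(df, cnvPath, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    written <- c(written, cnvPath)
  }
  if (!is.null(zPath)) {
    z <- truth@zScaffolds
    df <- data.frame(chrom = z, start = 0L,
                     end = truth@scaffoldLengths[z], name = "Z")
    write.table(df, zPath, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    written <- c(written, zPath)
  }
  invisible(written)
}
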