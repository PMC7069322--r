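#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame metadata metadata<-
#' @importFrom GenomicRanges GRanges seqnames start end width findOverlaps
#'   tileGenome granges
#' @importFrom GenomeInfoDb seqlengths seqlevels seqinfo Seqinfo
#' @importFrom IRanges IRanges Views ranges
#' @importFrom stats median rpois rnbinom rnorm runif sd lm coef residuals
#'   complete.cases setNames
#' @importFrom utils read.table write.table head
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Parameters for the two-sample coverage simulator
#'
#' `SimParams` bundles everything the synthetic-data generator needs to build
#' a multi-scaffold genome with autosomal and Z-linked scaffolds, and to draw
#' per-bin coverage counts for a focal (male, ZZ) and a comparison (female,
#' ZW) individual.
#'
#' The per-bin count mean is \eqn{\mu = \phi \cdot c \cdot b} where
#' \eqn{\phi} (`depthPerCopy`) is the mean per-base depth contributed by one
#' haploid copy, \eqn{c} the local copy number and \eqn{b} the bin size.
#' With `dispersion = 0` counts are Poisson; otherwise negative binomial with
#' variance \eqn{\mu(1 + \mathrm{dispersion}\cdot\mu)}.
#'
#' @slot nAutosomes number of autosomal scaffolds.
#' @slot nZScaffolds number of Z-linked scaffolds.
#' @slot scaffoldLength scaffold length in bp; must be a multiple of
#'   `binSize`.
#' @slot binSize bin width in bp (default 1000).
#' @slot depthPerCopy mean per-base depth per haploid copy (\eqn{\phi});
#'   default 15, so a diploid autosome averages 30x.
#' @slot dispersion non-negative overdispersion; 0 gives Poisson counts.
#' @slot libraryScaleComparison multiplicative library-size factor applied
#'   to the comparison sample.
#' @slot cnvSegments `GRanges` of planted copy-number segments with integer
#'   metadata columns `focalCopies` and `comparisonCopies`.
#' @slot gc target genome GC fraction for simulated sequence.
#' @slot seed integer seed; all RNG streams derive from it.
#'
#' @seealso [SimParams()], [simulateGenome()], [simulateCoverage()]
#' @exportClass SimParams
setClass("SimParams",
  representation(
    nAutosomes = "integer",
    nZScaffolds = "integer",
    scaffoldLength = "integer",
    binSize = "integer",
    depthPerCopy = "numeric",
    dispersion = "numeric",
    libraryScaleComparison = "numeric",
    cnvSegments = "GRanges",
    gc = "numeric",
    seed = "integer"
  )
)

setValidity("SimParams", function(object) {
  msg <- character()
  if (object@nAutosomes < 0L || object@nZScaffolds < 0L)
    msg <- c(msg, "scaffold counts must be non-negative")
  if (object@nAutosomes + object@nZScaffolds < 1L)
    msg <- c(msg, "at least one scaffold is required")
  if (object@scaffoldLength < 1L)
    msg <- c(msg, "scaffoldLength must be positive")
  if (object@binSize < 1L)
    msg <- c(msg, "binSize must be positive")
  if (object@scaffoldLength %% object@binSize != 0L)
    msg <- c(msg, "scaffoldLength must be a multiple of binSize")
  if (!is.finite(object@depthPerCopy) || object@depthPerCopy <= 0)
    msg <- c(msg, "depthPerCopy must be > 0")
  if (object@dispersion < 0)
    msg <- c(msg, "dispersion must be non-negative")
  if (object@libraryScaleComparison <= 0)
    msg <- c(msg, "libraryScaleComparison must be > 0")
  if (object@gc <= 0 || object@gc >= 1)
    msg <- c(msg, "gc must be in (0, 1)")
  cnv <- object@cnvSegments
  if (length(cnv) > 0L) {
    need <- c("focalCopies", "comparisonCopies")
    if (!all(need %in% colnames(mcols(cnv))))
      msg <- c(msg, "cnvSegments needs focalCopies and comparisonCopies")
    if (any(start(cnv) < 1L) || any(end(cnv) > object@scaffoldLength))
      msg <- c(msg, "cnvSegments must lie within scaffold bounds")
    hits <- findOverlaps(cnv, drop.self = TRUE, drop.redundant = TRUE)
    if (length(hits) > 0L)
      msg <- c(msg, "cnvSegments must not overlap each other")
  }
  if (length(msg)) msg else TRUE
})

#' Ground truth for a simulated genome
#'
#' Records which scaffolds are Z-linked and where copy-number segments were
#' planted, together with the per-segment expected coverage ratio
#' \eqn{r = c_{focal}/(c_{focal} + c_{comp})} that a library-size-corrected
#' two-sample scan should recover (0.5 for copy-number-neutral autosomal
#' bins).
#'
#' @slot zScaffolds character vector of Z-linked scaffold ids.
#' @slot cnvSegments `GRanges` with `focalCopies`, `comparisonCopies` and
#'   `expectedRatio` metadata columns.
#' @slot scaffoldLengths named integer vector of scaffold lengths.
#' @slot binSize bin width used when the truth was generated.
#'
#' @exportClass TruthSet
setClass("TruthSet",
  representation(
    zScaffolds = "character",
    cnvSegments = "GRanges",
    scaffoldLengths = "integer",
    binSize = "integer"
  )
)

setValidity("TruthSet", function(object) {
  msg <- character()
  if (is.null(names(object@scaffoldLengths)))
    msg <- c(msg, "scaffoldLengths must be named")
  if (!all(object@zScaffolds %in% names(object@scaffoldLengths)))
    msg <- c(msg, "zScaffolds must be a subset of scaffold names")
  er <- mcols(object@cnvSegments)$expectedRatio
  if (length(object@cnvSegments) > 0L &&
      (is.null(er) || any(er < 0) || any(er > 1)))
    msg <- c(msg, "expectedRatio must be present and within [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Binned coverage for one sample
#'
#' A `CoverageTrack` holds per-bin coverage (summed per-base depth, or read
#' counts) for one sample across all scaffolds of an assembly. Bins are
#' stored as a `GRanges` with a `count` metadata column; all scaffolds share
#' one bin size, with a possibly shorter last bin per scaffold.
#'
#' @slot sampleId sample identifier.
#' @slot binSize nominal bin width in bp.
#' @slot bins `GRanges` with numeric metadata column `count` (>= 0).
#'
#' @seealso [binCoverage()], [simulateCoverage()], [ratioScan()]
#' @exportClass CoverageTrack
setClass("CoverageTrack",
  representation(
    sampleId = "character",
    binSize = "integer",
    bins = "GRanges"
  )
)

setValidity("CoverageTrack", function(object) {
  msg <- character()
  cnt <- mcols(object@bins)$count
  if (is.null(cnt))
    msg <- c(msg, "bins must carry a 'count' metadata column")
  else if (any(!is.finite(cnt)) || any(cnt < 0))
    msg <- c(msg, "counts must be finite and non-negative")
  if (length(object@bins) > 0L && any(width(object@bins) > object@binSize))
    msg <- c(msg, "no bin may be wider than binSize")
  if (length(msg)) msg else TRUE
})

#' Assembly contiguity and composition metrics
#'
#' Scaffold-level summary of a genome assembly: counts, total and largest
#' scaffold length, N50/N75 with their L50/L75 ranks, NG50 against an
#' external genome-size estimate when one is supplied, GC percentage
#' (denominator excludes N bases) and N percentage.
#'
#' @slot nScaffolds number of scaffolds after the length filter.
#' @slot nGe1000 number of scaffolds of length >= 1000 bp.
#' @slot totalLength summed scaffold length (bp).
#' @slot largest largest scaffold length (bp).
#' @slot n50,n75 scaffold length at which the descending cumulative length
#'   first reaches 50% (75%) of the total.
#' @slot l50,l75 number of scaffolds up to and including the N50 (N75)
#'   scaffold.
#' @slot ng50 N50 computed against `genomeSize`, or `NULL` when no genome
#'   size was given or the assembly never reaches half of it.
#' @slot gcPct GC percentage over non-N bases.
#' @slot nPct percentage of N bases.
#' @slot minLen length filter that was applied (bp).
#' @slot genomeSize external genome-size estimate (bp) or `NULL`.
#'
#' @seealso [assemblyMetrics()]
#' @exportClass AssemblyMetrics
setClass("AssemblyMetrics",
  representation(
    nScaffolds = "integer",
    nGe1000 = "integer",
    totalLength = "numeric",
    largest = "numeric",
    n50 = "numeric",
    n75 = "numeric",
    l50 = "integer",
    l75 = "integer",
    ng50 = "numericOrNULL",
    gcPct = "numeric",
    nPct = "numeric",
    minLen = "numeric",
    genomeSize = "numericOrNULL"
  )
)

setValidity("AssemblyMetrics", function(object) {
  msg <- character()
  if (object@n50 < object@n75) msg <- c(msg, "n50 must be >= n75")
  if (object@l50 > object@l75) msg <- c(msg, "l50 must be <= l75")
  if (object@largest > object@totalLength)
    msg <- c(msg, "largest cannot exceed totalLength")
  if (object@gcPct < 0 || object@gcPct > 100 ||
      object@nPct < 0 || object@nPct > 100)
    msg <- c(msg, "percentages must be within [0, 100]")
  if (length(msg)) msg else TRUE
})

#' qPCR standard curve
#'
#' Ordinary least-squares fit of Ct on log10 starting copies over a dilution
#' series. The amplification efficiency is \eqn{E = 10^{-1/m} - 1} for slope
#' \eqn{m}; a perfect doubling per cycle gives \eqn{m = -3.3219} and
#' \eqn{E = 1}.
#'
#' @slot assayId assay identifier.
#' @slot points `data.frame` with columns `log10_copies` and `ct`.
#' @slot slope fitted slope (cycles per log10 copies, negative).
#' @slot intercept fitted intercept (Ct at 1 copy).
#' @slot efficiency amplification efficiency E.
#' @slot r.squared coefficient of determination of the fit.
#'
#' @seealso [fitStandardCurve()], [copiesFromCt()]
#' @exportClass StandardCurve
setClass("StandardCurve",
  representation(
    assayId = "character",
    points = "data.frame",
    slope = "numeric",
    intercept = "numeric",
    efficiency = "numeric",
    r.squared = "numeric"
  )
)

setValidity("StandardCurve", function(object) {
  msg <- character()
  if (nrow(object@points) < 3L)
    msg <- c(msg, "a standard curve needs at least 3 dilution points")
  if (length(unique(object@points$log10_copies)) < 3L)
    msg <- c(msg, "at least 3 distinct dilution levels are required")
  if (object@slope >= 0)
    msg <- c(msg, "slope must be negative (Ct decreases with input copies)")
  if (length(msg)) msg else TRUE
})
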