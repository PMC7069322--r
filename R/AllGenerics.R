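#' @rdname CoverageTrack-class
#' @param object,x a `CoverageTrack` (or other package object).
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))

#' @rdname CoverageTrack-class
#' @export
setGeneric("binSize", function(x) standardGeneric("binSize"))

#' @rdname CoverageTrack-class
#' @export
setGeneric("binRanges", function(x) standardGeneric("binRanges"))

#' @rdname CoverageTrack-class
#' @export
setGeneric("binCounts", function(x) standardGeneric("binCounts"))

#' @rdname CoverageTrack-class
#' @export
setGeneric("totalCount", function(x) standardGeneric("totalCount"))

#' @rdname TruthSet-class
#' @export
setGeneric("zScaffolds", function(x) standardGeneric("zScaffolds"))

#' @rdname TruthSet-class
#' @export
setGeneric("cnvSegments", function(x) standardGeneric("cnvSegments"))

#' @rdname TruthSet-class
#' @export
setGeneric("scaffoldLengths", function(x) standardGeneric("scaffoldLengths"))

#' @rdname StandardCurve-class
#' @export
setGeneric("efficiency", function(x) standardGeneric("efficiency"))

#' @rdname StandardCurve-class
#' @export
setGeneric("curveSlope", function(x) standardGeneric("curveSlope"))

#' @rdname StandardCurve-class
#' @export
setGeneric("curveIntercept", function(x) standardGeneric("curveIntercept"))

# ---- CoverageTrack methods ----

#' @rdname CoverageTrack-class
#' @export
setMethod("sampleId", "CoverageTrack", function(x) x@sampleId)

#' @rdname CoverageTrack-class
#' @export
setMethod("binSize", "CoverageTrack", function(x) x@binSize)

#' @rdname CoverageTrack-class
#' @export
setMethod("binRanges", "CoverageTrack", function(x) x@bins)

#' @rdname CoverageTrack-class
#' @export
setMethod("binCounts", "CoverageTrack", function(x) mcols(x@bins)$count)

#' @rdname CoverageTrack-class
#' @export
setMethod("totalCount", "CoverageTrack",
          function(x) sum(mcols(x@bins)$count))

setMethod("show", "CoverageTrack", function(object) {
  nsc <- length(unique(as.character(seqnames(object@bins))))
  cat("CoverageTrack '", object@sampleId, "': ",
      length(object@bins), " bins of ", object@binSize, " bp over ",
      nsc, " scaffold(s); total coverage ",
      format(totalCount(object), big.mark = ","), "\n", sep = "")
})

# ---- TruthSet methods ----

#' @rdname TruthSet-class
#' @export
setMethod("zScaffolds", "TruthSet", function(x) x@zScaffolds)

#' @rdname TruthSet-class
#' @export
setMethod("cnvSegments", "TruthSet", function(x) x@cnvSegments)

#' @rdname TruthSet-class
#' @export
setMethod("scaffoldLengths", "TruthSet", function(x) x@scaffoldLengths)

setMethod("show", "TruthSet", function(object) {
  cat("TruthSet: ", length(object@scaffoldLengths), " scaffold(s), ",
      length(object@zScaffolds), " Z-linked, ",
      length(object@cnvSegments), " planted CNV segment(s)\n", sep = "")
})

setMethod("show", "SimParams", function(object) {
  cat("SimParams: ", object@nAutosomes, " autosome(s) + ",
      object@nZScaffolds, " Z scaffold(s) of ",
      format(object@scaffoldLength, big.mark = ","), " bp; bin ",
      object@binSize, " bp; phi = ", object@depthPerCopy,
      " (diploid ~", 2 * object@depthPerCopy, "x); dispersion ",
      object@dispersion, "; comparison library scale ",
      object@libraryScaleComparison, "; ",
      length(object@cnvSegments), " CNV segment(s); seed ",
      object@seed, "\n", sep = "")
})

# ---- StandardCurve methods ----

#' @rdname StandardCurve-class
#' @export
setMethod("efficiency", "StandardCurve", function(x) x@efficiency)

#' @rdname StandardCurve-class
#' @export
setMethod("curveSlope", "StandardCurve", function(x) x@slope)

#' @rdname StandardCurve-class
#' @export
setMethod("curveIntercept", "StandardCurve", function(x) x@intercept)

setMethod("show", "StandardCurve", function(object) {
  cat("StandardCurve '", object@assayId, "': Ct = ",
      sprintf("%.4f", object@slope), " * log10(copies) + ",
      sprintf("%.4f", object@intercept), "; E = ",
      sprintf("%.1f%%", 100 * object@efficiency), ", R^2 = ",
      sprintf("%.4f", object@r.squared), " (",
      nrow(object@points), " points)\n", sep = "")
})

setMethod("show", "AssemblyMetrics", function(object) {
  fmt <- function(x) format(x, big.mark = ",", scientific = FALSE)
  cat("AssemblyMetrics (scaffolds >= ", fmt(object@minLen), " bp)\n",
      "  scaffolds:      ", fmt(object@nScaffolds),
      "  (>= 1 kb: ", fmt(object@nGe1000), ")\n",
      "  total length:   ", fmt(object@totalLength), " bp\n",
      "  largest:        ", fmt(object@largest), " bp\n",
      "  N50 / L50:      ", fmt(object@n50), " bp / ", fmt(object@l50), "\n",
      "  N75 / L75:      ", fmt(object@n75), " bp / ", fmt(object@l75), "\n",
      sep = "")
  if (!is.null(object@ng50))
    cat("  NG50:           ", fmt(object@ng50), " bp (genome size ",
        fmt(object@genomeSize), " bp)\n", sep = "")
  cat("  GC%: ", sprintf("%.2f", object@gcPct),
      "   N%: ", sprintf("%.2f", object@nPct), "\n", sep = "")
})
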