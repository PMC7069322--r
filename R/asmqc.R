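# Assembly contiguity and composition metrics.

#' Read assembly scaffolds and per-scaffold base composition
#'
#' Reads a (possibly gzipped, multi-line) FASTA and tabulates, per scaffold,
#' its length, G+C count and N count. Counting is case-insensitive; IUPAC
#' ambiguity codes other than N contribute to length but not to the GC
#' count.
#'
#' @param path FASTA file of assembly scaffolds.
#' @return A `data.frame` with columns `id`, `length`, `gc_count`,
#'   `n_count`.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">s1", "ACGT", ">s2", "NNNN"), fa)
#' readScaffolds(fa)
#' @export
readScaffolds <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L)
    stop("no sequences found in ", path)
  scaffoldStats(seqs)
}

#' @rdname readScaffolds
#' @param seqs a named [Biostrings::DNAStringSet].
#' @export
scaffoldStats <- function(seqs) {
  ids <- names(seqs)
  if (is.null(ids) || anyDuplicated(ids))
    stop("scaffolds must carry unique ids")
  freq <- Biostrings::alphabetFrequency(seqs, baseOnly = FALSE)
  data.frame(id = ids,
             length = Biostrings::width(seqs),
             gc_count = freq[, "C"] + freq[, "G"],
             n_count = freq[, "N"],
             stringsAsFactors = FALSE)
}

# first index at which the descending cumulative length reaches frac of ref
.nxx <- function(sortedLengths, ref, frac) {
  cum <- cumsum(as.numeric(sortedLengths))
  idx <- which(cum >= frac * ref)[1]
  if (is.na(idx)) return(NULL)
  list(n = sortedLengths[idx], l = idx)
}

#' Compute assembly metrics
#'
#' Scaffolds shorter than `minLen` are dropped first (inclusive threshold:
#' a scaffold of exactly `minLen` bp is kept). N50 is the length of the
#' scaffold at which the descending cumulative length first reaches >= 50%
#' of the filtered total, L50 the number of scaffolds up to and including
#' it; N75/L75 analogously at 75%. When `genomeSize` (or `genomeSizePg`,
#' converted at 0.978 Gbp/pg) is supplied, NG50 uses that size as the
#' denominator instead of the assembly total; it is undefined (NULL) when
#' the assembly never reaches half the genome size. The GC percentage
#' excludes N bases from its denominator.
#'
#' @param scaffolds a `data.frame` as returned by [readScaffolds()], a
#'   [Biostrings::DNAStringSet], or a bare numeric vector of lengths (GC
#'   and N percentages are then reported as 0).
#' @param minLen minimum scaffold length retained (bp).
#' @param genomeSize external genome-size estimate in bp, or `NULL`.
#' @param genomeSizePg alternatively, a C-value in pg, converted with
#'   [cvalueToGbp()].
#' @return An [AssemblyMetrics-class] object.
#' @examples
#' assemblyMetrics(c(1200, 600, 400), minLen = 500)
#' @export
assemblyMetrics <- function(scaffolds, minLen = 500,
                            genomeSize = NULL, genomeSizePg = NULL) {
  if (is(scaffolds, "DNAStringSet")) scaffolds <- scaffoldStats(scaffolds)
  if (is.numeric(scaffolds))
    scaffolds <- data.frame(id = as.character(seq_along(scaffolds)),
                            length = scaffolds, gc_count = 0, n_count = 0)
  stopifnot(all(c("length", "gc_count", "n_count") %in% names(scaffolds)))
  keep <- scaffolds$length >= minLen
  if (!any(keep))
    stop("no scaffolds of length >= ", minLen, " bp")
  sc <- scaffolds[keep, , drop = FALSE]
  lens <- sort(sc$length, decreasing = TRUE)
  total <- sum(as.numeric(lens))

  n50 <- .nxx(lens, total, 0.50)
  n75 <- .nxx(lens, total, 0.75)
  if (!is.null(genomeSizePg)) {
    if (!is.null(genomeSize))
      stop("give genomeSize or genomeSizePg, not both")
    genomeSize <- cvalueToGbp(genomeSizePg) * 1e9
  }
  ng50 <- if (!is.null(genomeSize)) .nxx(lens, genomeSize, 0.50) else NULL

  nonN <- sum(as.numeric(sc$length)) - sum(as.numeric(sc$n_count))
  gcPct <- if (nonN > 0) 100 * sum(as.numeric(sc$gc_count)) / nonN else 0
  new("AssemblyMetrics",
      nScaffolds = nrow(sc),
      nGe1000 = sum(sc$length >= 1000),
      totalLength = total,
      largest = as.numeric(lens[1]),
      n50 = as.numeric(n50$n), n75 = as.numeric(n75$n),
      l50 = as.integer(n50$l), l75 = as.integer(n75$l),
      ng50 = if (is.null(ng50)) NULL else as.numeric(ng50$n),
      gcPct = gcPct,
      nPct = 100 * sum(as.numeric(sc$n_count)) / total,
      minLen = as.numeric(minLen),
      genomeSize = if (is.null(genomeSize)) NULL else as.numeric(genomeSize))
}

#' Coerce AssemblyMetrics to a one-row data.frame
#'
#' @param x an [AssemblyMetrics-class] object.
#' @param ... ignored.
#' @export
as.data.frame.AssemblyMetrics <- function(x, ...) {
  data.frame(n_scaffolds = x@nScaffolds, n_ge_1000 = x@nGe1000,
             total_length = x@totalLength, largest = x@largest,
             n50 = x@n50, n75 = x@n75, l50 = x@l50, l75 = x@l75,
             ng50 = ifelse(is.null(x@ng50), NA_real_, x@ng50),
             gc_pct = x@gcPct, n_pct = x@nPct)
}

#' Cumulative scaffold curve
#'
#' Orders scaffolds from largest to smallest and reports, for each k, the
#' percentage of the assembly covered by the k largest scaffolds — the
#' curve used to compare assembly contiguity between genomes.
#'
#' @param scaffolds as in [assemblyMetrics()].
#' @param minLen minimum scaffold length retained (bp).
#' @return A `data.frame` with columns `k` and `pct` (monotone
#'   non-decreasing, ending at 100).
#' @examples
#' cumulativeCurve(c(100, 300))
#' scaffoldsForPct(cumulativeCurve(c(100, 300)), 75)
#' @export
cumulativeCurve <- function(scaffolds, minLen = 0) {
  if (is(scaffolds, "DNAStringSet")) scaffolds <- scaffoldStats(scaffolds)
  lens <- if (is.numeric(scaffolds)) scaffolds else scaffolds$length
  lens <- sort(lens[lens >= minLen], decreasing = TRUE)
  if (length(lens) == 0L) stop("no scaffolds to summarize")
  data.frame(k = seq_along(lens),
             pct = 100 * cumsum(as.numeric(lens)) / sum(as.numeric(lens)))
}

#' @rdname cumulativeCurve
#' @param curve a curve from [cumulativeCurve()].
#' @param pct target percentage of the assembly.
#' @return `scaffoldsForPct`: the smallest k whose cumulative percentage
#'   reaches `pct`.
#' @export
scaffoldsForPct <- function(curve, pct) {
  idx <- which(curve$pct >= pct)[1]
  if (is.na(idx)) stop("curve never reaches ", pct, "%")
  curve$k[idx]
}

#' Convert a C-value to genome size
#'
#' Haploid DNA mass in picograms converts to base pairs at 0.978 Gbp per
#' pg. Rounding to two decimals is left to reporting.
#'
#' @param cValue C-value(s) in pg (> 0).
#' @return Genome size(s) in Gbp.
#' @examples
#' round(cvalueToGbp(c(1.73, 1.53)), 2)   # 1.69 1.50
#' @export
cvalueToGbp <- function(cValue) {
  if (any(!is.finite(cValue)) || any(cValue <= 0))
    stop("C-values must be positive")
  cValue * 0.978
}
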