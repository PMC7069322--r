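# Z-chromosome scaffold assignment from male:female coverage folds.
#
# In birds males are ZZ and females ZW, so Z-linked scaffolds show half the
# female coverage: the library-corrected male:female fold sits near 2 on the
# Z and near 1 on autosomes.

#' Per-scaffold male:female coverage fold
#'
#' For each scaffold, the median over informative bins of e / (s * a),
#' where e and a are the male and female binned coverages and s the
#' library-size scale (estimate it with [libraryScale()], mode
#' `"median-recenter"`, so autosomal-like bins centre the fold at 1).
#' Bins with zero coverage in either sample are uninformative; scaffolds
#' with fewer than `minBins` informative bins are dropped. The median is
#' deliberately robust to CNV segments embedded in a scaffold.
#'
#' @param male,female [CoverageTrack-class] objects on identical bins.
#' @param s library-size scale factor; estimated from the tracks when
#'   `NULL`.
#' @param minBins minimum informative bins per scaffold.
#' @return A `data.frame` with columns `scaffold`, `length`, `median_fold`,
#'   `n_bins`.
#' @export
scaffoldFold <- function(male, female, s = NULL, minBins = 10L) {
  .checkComparable(male, female)
  if (is.null(s)) s <- libraryScale(male, female)
  if (!is.finite(s) || s <= 0) stop("s must be positive")
  bins <- binRanges(male)
  e <- binCounts(male); a <- s * binCounts(female)
  sq <- as.character(seqnames(bins))
  ok <- e > 0 & a > 0
  res <- lapply(split(seq_along(bins), sq), function(idx) {
    inf <- idx[ok[idx]]
    data.frame(length = sum(width(bins)[idx]),
               median_fold = if (length(inf) >= minBins)
                 median(e[inf] / a[inf]) else NA_real_,
               n_bins = length(inf))
  })
  out <- do.call(rbind, res)
  out <- data.frame(scaffold = names(res), out, row.names = NULL,
                    stringsAsFactors = FALSE)
  out[!is.na(out$median_fold), , drop = FALSE]
}

#' Classify scaffolds as Z-linked or autosomal
#'
#' A scaffold whose median male:female fold falls inside `zBand` is called
#' `Z`; inside `autoBand`, `autosome`; anywhere else, `ambiguous` — kept as
#' its own class because coverage folds between the bands are genuinely
#' uninformative and forcing a binary call risks misassignment. Scaffolds
#' shorter than `minLen` are excluded before classification and from the
#' summary denominators.
#'
#' @param folds `data.frame` from [scaffoldFold()].
#' @param zBand inclusive fold window called Z (default 1.6–2.6, centred
#'   on the expected twofold).
#' @param autoBand inclusive fold window called autosome (default
#'   0.8–1.25).
#' @param minLen minimum scaffold length considered (bp).
#' @return A list with `calls` (`data.frame` adding a `call` column) and
#'   `summary` (`data.frame` with `n_z`, `z_bp`, `total_bp`, `z_pct`).
#' @examples
#' f <- data.frame(scaffold = c("a", "z"), length = c(2e5, 1e5),
#'                 median_fold = c(1.01, 2.05), n_bins = c(200, 100))
#' classifyScaffolds(f)$summary
#' @export
classifyScaffolds <- function(folds, zBand = c(1.6, 2.6),
                              autoBand = c(0.8, 1.25), minLen = 10000) {
  stopifnot(all(c("scaffold", "length", "median_fold") %in% names(folds)))
  if (length(zBand) != 2L || length(autoBand) != 2L ||
      zBand[1] > zBand[2] || autoBand[1] > autoBand[2])
    stop("bands must be (lo, hi) with lo <= hi")
  if (autoBand[2] >= zBand[1] && zBand[2] >= autoBand[1])
    stop("zBand and autoBand must be disjoint")
  keep <- folds$length >= minLen
  calls <- folds[keep, , drop = FALSE]
  f <- calls$median_fold
  calls$call <- ifelse(f >= zBand[1] & f <= zBand[2], "Z",
                ifelse(f >= autoBand[1] & f <= autoBand[2], "autosome",
                       "ambiguous"))
  isZ <- calls$call == "Z"
  totalBp <- sum(as.numeric(calls$length))
  summary <- data.frame(n_z = sum(isZ),
                        z_bp = sum(as.numeric(calls$length[isZ])),
                        total_bp = totalBp,
                        z_pct = 100 * sum(as.numeric(calls$length[isZ])) /
                          totalBp)
  list(calls = calls, summary = summary)
}
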