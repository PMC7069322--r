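# Relative copy-number quantification from qPCR Ct tables.

#' Fit a qPCR standard curve
#'
#' Ordinary least squares of Ct on log10 starting copies over a dilution
#' series of at least three distinct levels. Reports slope, intercept,
#' amplification efficiency E = 10^(-1/slope) - 1 and R-squared. A perfect
#' doubling per cycle corresponds to slope -1/log10(2) = -3.3219 and
#' E = 100%.
#'
#' @param points `data.frame` with columns `log10_copies` and `ct` (one
#'   row per measured dilution point; replicates allowed).
#' @param assayId assay label.
#' @return A [StandardCurve-class].
#' @examples
#' pts <- data.frame(log10_copies = 3:7, ct = -3.3219 * (3:7) + 40)
#' fitStandardCurve(pts)
#' @export
fitStandardCurve <- function(points, assayId = "assay") {
  stopifnot(is.data.frame(points),
            all(c("log10_copies", "ct") %in% names(points)))
  points <- points[complete.cases(points[, c("log10_copies", "ct")]), ]
  if (length(unique(points$log10_copies)) < 3L)
    stop("a standard curve needs >= 3 distinct dilution levels")
  if (sd(points$log10_copies) == 0)
    stop("dilution levels have zero variance")
  fit <- lm(ct ~ log10_copies, data = points)
  slope <- unname(coef(fit)[2]); intercept <- unname(coef(fit)[1])
  if (!is.finite(slope) || slope >= 0)
    stop("fitted slope must be negative; check the dilution series")
  ssTot <- sum((points$ct - mean(points$ct))^2)
  r2 <- if (ssTot > 0) 1 - sum(residuals(fit)^2) / ssTot else 1
  new("StandardCurve", assayId = assayId,
      points = points[, c("log10_copies", "ct")],
      slope = slope, intercept = intercept,
      efficiency = 10^(-1 / slope) - 1, r.squared = r2)
}

#' Invert a standard curve: copies from Ct
#'
#' @param curve a [StandardCurve-class].
#' @param ct Ct value(s).
#' @return Estimated starting copies, `10^((ct - intercept) / slope)`.
#' @export
copiesFromCt <- function(curve, ct) {
  stopifnot(is(curve, "StandardCurve"))
  10^((ct - curve@intercept) / curve@slope)
}

#' Replicate QC for Ct values
#'
#' Replicates fail QC when any pairwise Ct difference exceeds `maxDelta`
#' (strictly: a spread of exactly `maxDelta` passes). The default 0.3
#' cycles is the conventional acceptance window for technical duplicates.
#'
#' @param ct numeric vector of replicate Ct values.
#' @param maxDelta maximum tolerated pairwise difference in cycles.
#' @param singleReplicate `"flag"` (fail QC, the default) or `"accept"`
#'   when only one replicate is present.
#' @return A list with `qcPass` (logical), `meanCt` (mean Ct when passing,
#'   otherwise `NA`) and `maxDelta` (the observed spread).
#' @examples
#' duplicateQc(c(20.0, 20.2))   # pass, mean 20.1
#' duplicateQc(c(20.0, 20.4))   # fail
#' @export
duplicateQc <- function(ct, maxDelta = 0.3,
                        singleReplicate = c("flag", "accept")) {
  singleReplicate <- match.arg(singleReplicate)
  ct <- ct[is.finite(ct)]
  if (length(ct) == 0L)
    return(list(qcPass = FALSE, meanCt = NA_real_, maxDelta = NA_real_))
  if (length(ct) == 1L) {
    pass <- singleReplicate == "accept"
    return(list(qcPass = pass, meanCt = if (pass) ct else NA_real_,
                maxDelta = 0))
  }
  spread <- max(ct) - min(ct)
  # strict "more than" rule, robust to binary floating point (20.3 - 20.0)
  pass <- spread <= maxDelta + sqrt(.Machine$double.eps)
  list(qcPass = pass, meanCt = if (pass) mean(ct) else NA_real_,
       maxDelta = spread)
}

#' Relative copy number of a target over a control assay
#'
#' Each assay's QC-passed mean Ct is inverted through its own standard
#' curve to absolute starting copies, and the ratio
#' copies(target) / copies(control) is returned. Inputs failing replicate
#' QC yield `NA` with the reason recorded.
#'
#' @param targetCt,controlCt replicate Ct vectors for the target and
#'   control assays.
#' @param targetCurve,controlCurve the assays' [StandardCurve-class]
#'   objects (the control curve defaults to the target curve).
#' @param maxDelta replicate-QC window in cycles.
#' @return A list with `ratio`, `copiesTarget`, `copiesControl`, `qcPass`
#'   and `reason`.
#' @export
relativeCopyNumber <- function(targetCt, controlCt, targetCurve,
                               controlCurve = targetCurve, maxDelta = 0.3) {
  qt <- duplicateQc(targetCt, maxDelta)
  qc <- duplicateQc(controlCt, maxDelta)
  if (!qt$qcPass || !qc$qcPass) {
    reason <- paste0(
      if (!qt$qcPass) "target replicates exceed maxDelta" else "",
      if (!qt$qcPass && !qc$qcPass) "; " else "",
      if (!qc$qcPass) "control replicates exceed maxDelta" else "")
    return(list(ratio = NA_real_, copiesTarget = NA_real_,
                copiesControl = NA_real_, qcPass = FALSE, reason = reason))
  }
  copT <- copiesFromCt(targetCurve, qt$meanCt)
  copC <- copiesFromCt(controlCurve, qc$meanCt)
  list(ratio = copT / copC, copiesTarget = copT, copiesControl = copC,
       qcPass = TRUE, reason = "")
}

#' Quantify a full qPCR Ct table
#'
#' Consumes a long-format table with one row per well: columns
#' `sample_id`, `assay_id`, `ct`, optionally `group`, `role` and
#' `log10_copies`. Rows with `role == "standard"` are used to fit one
#' standard curve per assay (unless `curves` are supplied); rows with
#' `role == "unknown"` (or no role column) are quantified. Exactly two
#' assays are expected: `target` and `control` (override with the
#' arguments). Mode `"curve"` converts each assay's QC-passed mean Ct to
#' absolute copies through its own curve; mode `"ddct"` computes
#' 2^-(dCt_sample) relative quantities assuming perfect efficiency, which
#' needs no curve.
#'
#' @param table the Ct table (`data.frame`).
#' @param curves optional named list of [StandardCurve-class] objects per
#'   assay.
#' @param targetAssay,controlAssay assay ids.
#' @param maxDelta replicate-QC window in cycles.
#' @param mode `"curve"` (default) or `"ddct"`.
#' @return A list with `samples` (`data.frame`: `sample_id`, `group`,
#'   `qc_pass`, `reason`, `ct_target`, `ct_control`, `ratio`) and
#'   `groups` (`data.frame`: `group`, `n`, `mean_ratio`, `sd_ratio`).
#' @examples
#' tab <- simulateQpcr(2, perfectCurve(), noiseSd = 0)
#' quantifyQpcr(tab, curves = list(target = perfectCurve(),
#'                                 control = perfectCurve()))$samples
#' @export
quantifyQpcr <- function(table, curves = NULL, targetAssay = "target",
                         controlAssay = "control", maxDelta = 0.3,
                         mode = c("curve", "ddct")) {
  mode <- match.arg(mode)
  stopifnot(all(c("sample_id", "assay_id", "ct") %in% names(table)))
  if (!"role" %in% names(table)) table$role <- "unknown"
  if (!"group" %in% names(table)) table$group <- "all"

  std <- table[table$role == "standard", , drop = FALSE]
  if (mode == "curve" && is.null(curves)) {
    if (nrow(std) == 0L)
      stop("mode 'curve' needs standards in the table or explicit curves")
    curves <- lapply(split(std, std$assay_id), function(df)
      fitStandardCurve(data.frame(log10_copies = df$log10_copies,
                                  ct = df$ct),
                       assayId = df$assay_id[1]))
  }
  unk <- table[table$role != "standard", , drop = FALSE]
  samples <- do.call(rbind, lapply(split(unk, unk$sample_id), function(df) {
    tgt <- df$ct[df$assay_id == targetAssay]
    ctl <- df$ct[df$assay_id == controlAssay]
    qt <- duplicateQc(tgt, maxDelta); qc <- duplicateQc(ctl, maxDelta)
    pass <- qt$qcPass && qc$qcPass
    ratio <- NA_real_
    if (pass) {
      ratio <- if (mode == "curve") {
        relativeCopyNumber(tgt, ctl, curves[[targetAssay]],
                           curves[[controlAssay]], maxDelta)$ratio
      } else {
        2^-(qt$meanCt - qc$meanCt)
      }
    }
    data.frame(sample_id = df$sample_id[1], group = df$group[1],
               qc_pass = pass,
               reason = if (pass) "" else "replicate spread > maxDelta",
               ct_target = qt$meanCt, ct_control = qc$meanCt,
               ratio = ratio, stringsAsFactors = FALSE)
  }))
  row.names(samples) <- NULL
  ok <- samples[samples$qc_pass, , drop = FALSE]
  groups <- do.call(rbind, lapply(split(ok, ok$group), function(df)
    data.frame(group = df$group[1], n = nrow(df),
               mean_ratio = mean(df$ratio), sd_ratio = sd(df$ratio))))
  row.names(groups) <- NULL
  list(samples = samples, groups = groups)
}
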