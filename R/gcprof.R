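# GC-content profiling of gene regions and GC-stratified exon recovery.

#' GC class labels
#'
#' The five GC classes used throughout the package, from GC-richest to
#' GC-poorest, with inclusive lower bounds: a GC of exactly 60% falls in
#' "60-69", and 69.99% does too.
#'
#' @return Character vector of class labels, in display order.
#' @export
gcClassLevels <- function() c(">=70", "60-69", "50-59", "40-49", "<40")

# fractional [lo, hi) bounds per class (hi of the top class is inclusive 1)
.gcClassBounds <- function(class) {
  switch(class,
         ">=70" = c(0.70, 1.0000001),
         "60-69" = c(0.60, 0.70),
         "50-59" = c(0.50, 0.60),
         "40-49" = c(0.40, 0.50),
         "<40" = c(0, 0.40),
         stop("unknown GC class: ", class))
}

#' Assign GC percentages to GC classes
#'
#' @param gcPct numeric GC percentages (0–100).
#' @return Factor with levels [gcClassLevels()].
#' @examples
#' gcClassOf(c(72, 69.99, 39.9))
#' @export
gcClassOf <- function(gcPct) {
  cut(gcPct, breaks = c(-Inf, 40, 50, 60, 70, Inf), right = FALSE,
      labels = rev(gcClassLevels())) |>
    factor(levels = gcClassLevels())
}

#' GC percentage of sequences, ignoring N bases
#'
#' @param seqs a [Biostrings::DNAStringSet] or character vector.
#' @return Numeric GC percentages; `NA` for sequences with no non-N base.
#' @export
gcPercent <- function(seqs) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  freq <- Biostrings::alphabetFrequency(seqs, baseOnly = TRUE)
  acgt <- rowSums(freq[, c("A", "C", "G", "T"), drop = FALSE])
  ifelse(acgt > 0, 100 * (freq[, "C"] + freq[, "G"]) / acgt, NA_real_)
}

#' Read gene models from GFF3
#'
#' Extracts 5'UTR, CDS and 3'UTR features and returns the flat region
#' table [gcByRegion()] consumes. Feature types `five_prime_UTR`, `CDS`
#' and `three_prime_UTR` are mapped to kinds `five_prime_utr`, `cds`,
#' `three_prime_utr`; gene assignment uses the `Parent` (or `ID`)
#' attribute.
#'
#' @param path a GFF3 file.
#' @return A `data.frame` with columns `gene_id`, `scaffold`, `strand`,
#'   `kind`, `start`, `end` (1-based, inclusive).
#' @export
readGeneModels <- function(path) {
  gff <- rtracklayer::import(path, format = "gff3")
  typeMap <- c(five_prime_UTR = "five_prime_utr", CDS = "cds",
               three_prime_UTR = "three_prime_utr")
  gff <- gff[as.character(gff$type) %in% names(typeMap)]
  if (length(gff) == 0L) stop("no UTR/CDS features in ", path)
  parent <- as.character(S4Vectors::unstrsplit(gff$Parent, ","))
  parent[parent == ""] <- as.character(gff$ID[parent == ""])
  data.frame(gene_id = sub("^(transcript|mRNA)[:.]", "", parent),
             scaffold = as.character(seqnames(gff)),
             strand = as.character(GenomicRanges::strand(gff)),
             kind = unname(typeMap[as.character(gff$type)]),
             start = start(gff), end = end(gff),
             stringsAsFactors = FALSE)
}

#' Mean and SD of GC content per gene region
#'
#' For each gene, the regions of one kind (5'UTR, CDS, 3'UTR) are
#' concatenated and a single GC percentage computed (N bases excluded from
#' the denominator); the mean and standard deviation across genes are then
#' reported per kind. Minus-strand regions are reverse-complemented before
#' concatenation — irrelevant to GC itself, but it keeps exported
#' sequences in transcript orientation.
#'
#' @param genes a `data.frame` with columns `gene_id`, `scaffold`,
#'   `strand`, `kind`, `start`, `end` (1-based, inclusive), e.g. from
#'   [readGeneModels()].
#' @param sequences a named [Biostrings::DNAStringSet] covering all
#'   referenced coordinates.
#' @return A `data.frame` with columns `kind`, `n_genes`, `mean_gc`,
#'   `sd_gc`.
#' @export
gcByRegion <- function(genes, sequences) {
  need <- c("gene_id", "scaffold", "strand", "kind", "start", "end")
  stopifnot(all(need %in% names(genes)))
  bad <- setdiff(unique(genes$scaffold), names(sequences))
  if (length(bad))
    stop("scaffolds absent from sequences: ", paste(bad, collapse = ", "))
  lens <- setNames(Biostrings::width(sequences), names(sequences))
  if (any(genes$start < 1L) || any(genes$end > lens[genes$scaffold]))
    stop("gene region outside its scaffold sequence")

  geneKindGc <- function(df) {
    pieces <- vapply(seq_len(nrow(df)), function(i) {
      s <- Biostrings::subseq(sequences[[df$scaffold[i]]],
                              df$start[i], df$end[i])
      if (df$strand[i] == "-") s <- Biostrings::reverseComplement(s)
      as.character(s)
    }, character(1))
    gcPercent(paste(pieces, collapse = ""))
  }
  kinds <- c("five_prime_utr", "cds", "three_prime_utr")
  rows <- lapply(kinds, function(k) {
    sub <- genes[genes$kind == k, , drop = FALSE]
    if (nrow(sub) == 0L)
      return(data.frame(kind = k, n_genes = 0L, mean_gc = NA_real_,
                        sd_gc = NA_real_))
    perGene <- vapply(split(sub, sub$gene_id), geneKindGc, numeric(1))
    data.frame(kind = k, n_genes = length(perGene),
               mean_gc = mean(perGene, na.rm = TRUE),
               sd_gc = sd(perGene, na.rm = TRUE))
  })
  do.call(rbind, rows)
}

#' Exon recovery from an assembly, stratified by GC class
#'
#' An exon counts as recovered when its best local alignment to any
#' assembly scaffold covers at least `minCov` of the exon length at an
#' identity of at least `minIdent` (matches over aligned exon bases).
#' Recovery percentages are reported per GC class; classes with no exons
#' are reported as `NA`, not 0. This operationalizes "present in the
#' assembly" for short GC-rich exons that short-read assemblies tend to
#' drop.
#'
#' @param exons a [Biostrings::DNAStringSet]; GC classes are taken from a
#'   `gcClass` metadata column (as set by [simulateExons()]) or computed
#'   from the sequences.
#' @param assembly a [Biostrings::DNAStringSet] of scaffolds, or a FASTA
#'   path.
#' @param minCov minimum aligned fraction of the exon (default 0.8).
#' @param minIdent minimum identity over aligned exon bases (default 0.9).
#' @return A list with `perExon` (`data.frame`: `exon`, `gc_class`,
#'   `coverage`, `identity`, `recovered`) and `perClass` (`data.frame`:
#'   `gc_class`, `n`, `recovered_pct`).
#' @export
exon1Recovery <- function(exons, assembly, minCov = 0.8, minIdent = 0.9) {
  if (is.character(assembly)) assembly <- Biostrings::readDNAStringSet(assembly)
  stopifnot(is(exons, "DNAStringSet"), length(assembly) > 0L)
  cls <- mcols(exons)$gcClass
  if (is.null(cls)) cls <- gcClassOf(gcPercent(exons))
  cls <- factor(as.character(cls), levels = gcClassLevels())

  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                  baseOnly = TRUE)
  alignOne <- function(exon) {
    best <- c(coverage = 0, identity = 0)
    bestMatches <- -1
    for (i in seq_along(assembly)) {
      aln <- Biostrings::pairwiseAlignment(
        exon, assembly[[i]], type = "local",
        substitutionMatrix = mat, gapOpening = 4, gapExtension = 2)
      pat <- Biostrings::pattern(aln)
      span <- end(pat) - start(pat) + 1L   # exon bases inside the alignment
      nm <- Biostrings::nmatch(aln)
      if (nm > bestMatches && span > 0) {
        bestMatches <- nm
        best <- c(coverage = span / length(exon), identity = nm / span)
      }
    }
    best
  }
  res <- t(vapply(seq_along(exons), function(i) alignOne(exons[[i]]),
                  c(coverage = 0, identity = 0)))
  perExon <- data.frame(
    exon = if (is.null(names(exons))) as.character(seq_along(exons)) else
      names(exons),
    gc_class = cls,
    coverage = res[, "coverage"], identity = res[, "identity"],
    recovered = res[, "coverage"] >= minCov & res[, "identity"] >= minIdent,
    stringsAsFactors = FALSE)
  perClass <- do.call(rbind, lapply(gcClassLevels(), function(k) {
    sub <- perExon[perExon$gc_class == k, , drop = FALSE]
    data.frame(gc_class = k, n = nrow(sub),
               recovered_pct = if (nrow(sub) > 0)
                 100 * mean(sub$recovered) else NA_real_)
  }))
  list(perExon = perExon, perClass = perClass)
}
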