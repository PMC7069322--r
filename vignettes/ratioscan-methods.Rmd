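---
title: "Methods: two-sample coverage-ratio scanning and its companion analyses"
author: "ratioscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample coverage-ratio scanning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ratioscan)
```

## The model

Two individuals are sequenced and mapped to one assembly; coverage is
summed per fixed-width bin (default 1 kb). Writing $e_i$ and $a_i$ for the
focal and comparison coverage of bin $i$ and $s$ for a library-size scale,
the per-bin statistic is

$$ r_i = \frac{e_i}{e_i + s\,a_i}. $$

If bin $i$ carries $c_e$ copies in the focal and $c_a$ copies in the
comparison genome, and coverage is proportional to copy number, then
$\mathbb{E}[r_i] \approx c_e / (c_e + c_a)$ after correction. Three regimes
matter in practice:

* neutral diploid bins: $r \approx 1/2$;
* a comparison-side doubling ($c_e{=}2$, $c_a{=}4$): $r \approx 1/3$;
* Z-linked scaffolds against a ZW female: $c_a{=}1$ vs $c_e{=}2$, so
  $r \approx 2/3$, equivalently a male:female fold of 2.

A segment's comparison:focal fold is recovered from its mean ratio as
$(1-\bar r)/\bar r$. The statistic deliberately compares *reads* mapped to
one assembly rather than two assemblies to each other: assemblies of
unequal quality would confound biological differences with technical ones.

Assumptions: the two libraries are prepared and sequenced similarly enough
that a single multiplicative factor aligns them; mapping bias affects both
samples alike; bins are large enough that per-bin counts are well away
from zero at the working depth (at 30× and 1 kb, neutral bins hold
~30,000 summed bases of depth, giving $r$ a standard deviation of ~0.002).

## Library-size correction

How the correction constant is obtained is a genuinely open choice, so
both common answers are implemented:

* `totals`: $s = \sum e / \sum a$ — the literal coverage-ratio correction.
  It is biased by any large copy-number asymmetry, notably the Z
  chromosome itself (a ZW comparison library contributes half coverage on
  ~5% of an avian genome).
* `median-recenter` (default): $s = \mathrm{median}(e_i/a_i)$ over doubly
  covered bins, which fixes the genome-wide median of $r$ at exactly 0.5
  as the neutral expectation demands, and is robust to CNVs and Z
  scaffolds so long as they are a minority of bins.

On simulated data where planted CNVs cover ≲2% of bins the two agree to
within the CNV fraction; the package tests assert 2% agreement at a 1%
planted fraction.

## Segmentation

Bins with $r \le 0.40$ (`comparison_gain`) or $r \ge 0.60$
(`comparison_loss`) are chained into maximal runs, tolerating up to 2
interrupting bins, and runs of fewer than 5 qualifying bins are dropped.
At 30× Poisson coverage a neutral bin crosses either threshold with
probability far below $10^{-3}$, so with these defaults false segments are
effectively absent while a true 2×-comparison segment (expected
$r = 1/3$) qualifies in essentially every bin; recovery of planted 200-kb
segments is exact to the bin in the test suite. Bins whose combined
corrected coverage falls below `minCombined = 10` are masked and never
imputed: the ratio is undefined at zero coverage and wildly unstable just
above it. All thresholds are arguments.

Coordinates follow Bioconductor conventions internally (1-based closed
`GRanges`) and BED conventions (0-based half-open) in every file written.

## Sex-scaffold assignment

The per-scaffold fold is the *median* over informative bins of
$e/(s\,a)$ — median, not mean, so an embedded duplication does not drag an
autosomal scaffold toward the Z band (the worked example in the README
shows a scaffold with 40% of its length duplicated still scoring 0.989).
Scaffolds are called Z inside the fold band 1.6–2.6, autosome inside
0.8–1.25, and ambiguous elsewhere; the published analyses this mirrors do
not state their exact window, so the bands are this package's choice,
centred on the theoretical folds of 2 and 1 and kept asymmetric on the Z
side because folds inflate, never deflate, when the female library is thin
on Z. The ambiguous class is retained deliberately: forcing binary calls
is how small scaffolds end up misassigned. Defaults `minLen = 10` kb and
`minBins = 10` suppress scaffolds whose median fold is dominated by a
handful of bins. W-scaffold identification is out of scope — female-only
coverage on low-complexity sequence needs different evidence than a fold
statistic.

## Assembly metrics

N50 is the length of the scaffold at which the descending cumulative
length first reaches ≥50% of the total; L50 counts scaffolds up to and
including it; N75/L75 analogously. When the cumulative sum hits the
threshold exactly on a boundary, the scaffold reaching it is counted
(first-crossing rule). NG50 replaces the assembly total with an external
genome-size estimate, here obtainable from a C-value at 0.978 Gbp per pg,
and is reported as undefined when the assembly never reaches half the
genome size rather than silently falling back to N50. The length filter is
inclusive (≥ `minLen`, default 500 bp) and configurable, since reported
assembly statistics vary between ≥ and > conventions. GC% excludes N bases
from its denominator — ambiguity about this convention is common enough
that it is stated here and in the docs. The brute-force oracle in the test
suite rescans every descending-cumulative prefix on 1,000 random length
sets.

## GC profiling and exon recovery

Per gene, the regions of one kind (5'UTR, CDS, 3'UTR) are concatenated and
yield one GC value; means and standard deviations are taken across genes,
so long genes do not dominate. The five GC classes (≥70, 60–69, 50–59,
40–49, <40 %) use inclusive lower bounds: 69.99 is "60–69".

"Recovered from the assembly" is not a self-defining notion for an exon;
this package operationalizes it as a local alignment
(`Biostrings::pairwiseAlignment`, match 1 / mismatch −2 / gap open 4,
extend 2) covering ≥80% of the exon length at ≥90% identity over the
aligned exon bases. Both cutoffs are arguments, and recovery is provably
monotone in them (raising either can only lose exons). Classes with no
exons report `NA`, never 0%. Exhaustive per-scaffold alignment is quadratic
and intended for gene-panel scale (tens of exons against a test assembly),
not genome-wide screens.

## qPCR quantification

Standard curves are ordinary least squares of Ct on $\log_{10}$ copies
over ≥3 distinct dilution levels; efficiency is $E = 10^{-1/m} - 1$
(slope $-3.3219 \Rightarrow E = 100\%$). Quantification inverts each
assay's own curve at the replicate-mean Ct — absolute quantification, as
the confirmatory design this supports requires; a ΔΔCt mode (perfect
efficiency assumed, no curve needed) is available for quick checks.
Replicate QC generalizes the duplicate rule to $n$ replicates via the
maximum pairwise spread, failing when it exceeds 0.3 Ct; a spread of
exactly 0.3 passes ("more than" is strict, and the comparison carries a
square-root-of-epsilon guard so 20.3 − 20.0 is not failed by binary
floating point). Single replicates are flagged by default, acceptable by
argument. QC-failed samples propagate `NA` with a recorded reason instead
of vanishing.

## The simulator

`SimParams`/`simulateGenome`/`simulateCoverage` emulate the study design
the statistic assumes: a ZZ male focal individual and a ZW female
comparison individual over a multi-scaffold genome. Per-bin counts are
drawn with mean $\mu = \varphi\,c\,b\,\ell$ ($\varphi$ per-copy per-base
depth, $c$ local copy number, $b$ bin width, $\ell$ the sample's library
scale); dispersion 0 gives Poisson, otherwise negative binomial with
variance $\mu(1 + \delta\mu)$ (size $=1/\delta$) — the overdispersed
option exists because real mapped coverage is far more variable than
Poisson. Defaults: $\varphi = 15$, so diploid autosomes sit at ~30×, the
order of a typical short-read genome project; dispersion 0; equal library
sizes. The library scale enters the mean of a single draw rather than
multiplying drawn counts, keeping counts integer with the same
expectation. The male is the focal sample and the female the comparison
sample, matching the ZZ-focal/ZW-comparison design; planted CNV segments
carry separate focal and comparison copy numbers, and a bin straddling a
segment boundary receives the length-weighted mean copy number — which is
how a gene lying across a duplication breakpoint acquires its
half-duplicated coverage signature. One integer seed derives every stream
(genome, each sex's coverage, exons, Ct noise), so outputs are
bit-identical under a fixed seed.

What the simulator does *not* emulate — and what green tests therefore do
not certify about real data: read-level artefacts (errors, adapters,
duplicates), mappability and repeat-driven coverage holes, GC-dependent
coverage bias (listed as a possible extension), batch differences beyond a
scalar library factor, and W-chromosome sequence. On real tracks the
neutral ratio distribution is wider than Poisson predicts; the
segmentation defaults still apply but boundary precision degrades with
dispersion.

## Problem sizes

The packaged checks run at the scale the analyses are designed for while
staying laptop-friendly: calibration and duplication-recovery checks use
10 scaffolds × 1 Mb (10⁴ 1-kb bins) at 30×; the sex-assignment check uses
7 scaffolds × 100 kb over 20 independent seeds; the metric oracle uses
1,000 random length sets. `scripts/acceptance.R` re-runs the first two
from scratch under a caller-supplied seed.

## Known limitations

* The fold estimate $(1-\bar r)/\bar r$ reports coverage fold, not
  biological copy count: a region called at fold 2 may be a duplication on
  a diploid background (2→4 copies) or something more complex — a
  candidate region whose coverage excess reads as "twofold" can still
  correspond to a triplicated haplotype arrangement. Interpretation stays
  with the user, backed by qPCR.
* Scale factors assume one global library ratio; strong GC bias differing
  between libraries violates this.
* `callCnv` on a genome containing Z scaffolds against an opposite-sex
  comparison will report the entire Z as `comparison_loss`; run the sex
  scan first and treat Z scaffolds separately, as the worked example
  shows.
* BAM binning uses `Rsamtools::pileup`, which is convenient but not the
  fastest path for very large BAMs; pre-binned bedGraph input (e.g. from
  `bedtools genomecov -bga`) is the intended route at scale.
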