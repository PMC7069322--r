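Package: ratioscan
Title: Two-Sample Binned Coverage-Ratio Scanning, Sex-Scaffold Assignment
    and Assembly QC for Draft Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Comparative read-depth analyses for draft genome assemblies,
    centred on the per-bin coverage-ratio statistic r = e/(e + s*a) between a
    focal and a comparison sample: copy-number-variant detection from binned
    coverage tracks, Z-chromosome scaffold assignment from male:female
    coverage folds, assembly contiguity and composition metrics (N50, NG50,
    L50, cumulative scaffold curves, C-value genome-size conversion),
    GC-content profiling of gene regions with GC-stratified exon recovery,
    and qPCR relative copy-number quantification with standard curves and
    replicate QC. A synthetic-data generator produces multi-scaffold genomes
    with Z-linked scaffolds, planted copy-number segments, two-sample
    Poisson or negative-binomial coverage, GC-stratified exon sets and noisy
    Ct tables, so every analysis is testable end to end against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    Rsamtools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: CopyNumberVariation, Coverage, GenomeAssembly, QualityControl,
    Sequencing
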