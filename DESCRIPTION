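Package: pilecov
Title: Region and Single-Base Pileup Statistics for Targeted Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Characterizes whole-exome and targeted sequencing alignments at
    region and single-base resolution. Computes per-region mean depth of
    coverage, GC content and the maximal-coverage sub-region statistic;
    per-position allele-specific pileups with depth, variant allelic
    fraction and strand-specific counts; SNP pileups with VAF-threshold
    genotype assignment; and an on-the-fly PCR-duplicate filter based on
    soft-clip-corrected alignment coordinates and total mapping size, applied
    during traversal without writing intermediate alignment files. Includes a
    region-partitioned parallel engine with deterministic merged output, four
    tab-delimited output modes, a visual quality-control report generator,
    and a synthetic-fixture generator with a naive brute-force pileup oracle
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rsamtools,
    Biostrings,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    vcfR,
    optparse,
    parallel,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
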