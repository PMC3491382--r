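Package: methcall
Title: Joint SNP and DNA Methylation Calling from Bisulfite Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A Bayesian caller for directional bisulfite sequencing
    (WGBS/RRBS) that genotypes the ten diploid genotypes and quantifies
    per-cytosine methylation simultaneously from coordinate-sorted
    alignments. The observation model distinguishes bisulfite-affected
    reads (C-strand) from genotype-informative reads (G-strand), with
    explicit under- and over-conversion rates and three methylation-prior
    estimation modes (naive, context-specific, locus-specific). Includes
    bisulfite-aware empirical base-quality recalibration (thymines at
    reference cytosines treated as a fifth base), a five-prime
    non-conversion filter, site filters (strand bias, quality by depth,
    SNP clusters, MQ0 regions, depth), count-based comparator callers, a
    sensitivity/FDR evaluation harness, and a directional bisulfite read
    simulator producing reference FASTA, truth VCF, per-cytosine
    methylation tables, and SAM alignments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicAlignments,
    IRanges,
    Rsamtools,
    S4Vectors,
    VariantAnnotation,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
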