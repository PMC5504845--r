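Package: ssrminer
Title: Genic Microsatellite Mining and Marker Development from Transcriptome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovery of perfect microsatellites (simple sequence repeats,
    SSRs) in assembled transcript sequences and their development into PCR
    markers. Provides assembly summary statistics (N50, length distribution,
    GC content), a maximal perfect tandem-repeat scanner with per-unit-length
    minimum repeat thresholds, strand- and rotation-invariant motif-class
    canonicalization, compound-SSR detection, repeat-count summary tables,
    flanking-length and primer-constraint screening (primer length, melting
    temperature, product size), and marker polymorphism statistics (number of
    alleles, observed heterozygosity, polymorphic information content) from
    genotype tables.  Seed-reproducible synthetic sequence and genotype
    generators with known ground truth support validation, and a command-line
    interface exposes the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    rtracklayer,
    optparse,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
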