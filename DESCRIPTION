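Package: virolib
Title: Comparison of Viral Metagenome Libraries Across Preparation Treatments
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for asking whether library preparation choices (input DNA
    amount, adaptor-mediated amplification cycles, sequencing platform) change
    the composition of shotgun viral metagenomes. Implements per-read %G+C
    profiling over the first 50 bp in 2%-wide bins, duplicate-read spectra and
    artificial-duplicate detection by identical-start/identity clustering,
    translated k-mer recruitment of reads to protein clusters, assembly summary
    statistics (N50, maximum contig, total size), and pairwise Pearson
    correlation of library profiles with bootstrapped UPGMA clustering. A
    sequencing-library simulator with explicit ground truth (source fragments,
    PCR duplicates, adapter contamination, GC-dependent amplification bias)
    makes every stage testable without real sequencing data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    data.table,
    jsonlite,
    methods,
    S4Vectors,
    stats,
    tibble,
    utils,
    withr
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
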