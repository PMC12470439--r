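Package: dupscan
Title: Survey and Characterization of Recurrent Gene Duplications
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing recurrent gene duplications and
    repeat-embedded paralog arrays: pairwise sequence identity matrices and
    microsynteny classification, Nei-Gojobori dN/dS estimation with the
    codon-based Z-test of neutrality, codon-aware alignment trimming,
    Tamura-Nei (TN93) distances and neighbor-joining trees with bootstrap
    support, a small-RNA pipeline (read filtering, contaminant removal,
    mismatch-bounded mapping, locally-unique read attribution, stratified
    counting, coverage profiles, and the piRNA ping-pong z10 statistic),
    protein disorder/tandem-repeat/composition summaries, and seeded
    synthetic-data generators (codon evolution with duplication and gene
    conversion, repeat-array genomes, small-RNA libraries with tunable
    ping-pong bias) so every pipeline stage is testable against planted truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    rtracklayer,
    GenomicRanges,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
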