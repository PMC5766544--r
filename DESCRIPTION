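Package: genewalker
Title: Transcript-Seeded Iterative Local Assembly of Gene Models from
    Low-Coverage Whole-Genome Reads
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds per-gene genomic scaffolds (exons, introns and flanking
    sequence) from low-coverage paired-end whole-genome reads by walking
    outward from a reference transcript: read pairs dominated by high-copy
    repeats are removed by median 31-mer coverage filtering, the surviving
    reads are indexed for maximal-exact-match recruitment, recruited reads
    are assembled locally with a de Bruijn unitigger and merged by
    overlap-layout-consensus, and the walk iterates from contig ends until
    extension stalls.  Includes chimera splitting, per-gene scaffolding with
    fixed N-gaps, redundancy merging across splice variants, intron and
    flank reports, and a synthetic genome-and-reads simulator with ground
    truth for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
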