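Package: smurf16S
Title: Joint Microbial Community Profiling from Multiple 16S rRNA Amplicon Regions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Profiles a microbial community from short reads sequenced over
    several independently amplified 16S rRNA gene variable regions.  A
    protocol-specific k-mer database is built from a full-length reference
    (Greengenes/SILVA style FASTA plus taxonomy), reads are quality filtered,
    assigned to regions by primer and collapsed, and the relative abundances
    of full-length reference sequences are estimated jointly over all regions
    by an expectation-maximization fixed-point iteration on a convex
    likelihood.  Includes footprint-group resolution analysis with an
    effective-sequence-count (exponentiated Shannon entropy) ambiguity
    measure, an amplicon read simulator with power-law communities, weighted
    precision/recall evaluation, and a greedy region-ordering experiment.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    Biostrings,
    S4Vectors,
    jsonlite,
    yaml,
    methods,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
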