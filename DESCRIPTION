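Package: sumoarray
Title: Hit Calling and Enzyme-Substrate Network Analysis for Proteome
    Microarray SUMOylation Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for the in-silico arm of proteome microarray SUMOylation
    screens. Reads spot-quantified scans (GenePix GPR or generic TSV) against
    an array design, computes foreground/background ratios with block-median
    normalization, and calls substrates with a duplicate-spot
    standard-deviation rule, replicate consensus, negative-control removal and
    high-E1/E2 subtraction to derive E3 ligase-dependent substrate sets.
    Builds the E3/SUMO-isoform to substrate bipartite network with uniqueness,
    pairwise-sharing and SUMO isoform-preference statistics, scans protein
    sequences for the SUMOylation consensus motif and SUMO-interacting motifs,
    and performs hypergeometric over-representation analysis against the
    array background. A synthetic-array generator with planted ground truth
    and recovery scoring exercises every stage without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    igraph,
    Biostrings,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'conditions.R'
    'accessors.R'
    'array-io.R'
    'data-docs.R'
    'enrich.R'
    'hitcall.R'
    'motifscan.R'
    'netstats.R'
    'synthgen.R'
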