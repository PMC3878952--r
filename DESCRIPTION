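Package: icfp
Title: Expression-Guided Carbon Flux Path Finding in Metabolic Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Enumerates stoichiometrically balanced, carbon-tracking
    source-to-target paths through a metabolic network, ranked by a
    three-stage lexicographic mixed-integer objective driven by gene and
    protein expression data.  Reactions are first partitioned into
    highly, medium and lowly expressed sets via a threshold regression
    test on expression series (or a simple fold-change rule) propagated
    through gene-protein-reaction Boolean rules; paths are then found by
    minimising flux through lowly expressed reactions, then medium, then
    path length, with ranked enumeration by solution-elimination cuts.
    Includes a built-in branch-and-bound solver, a brute-force reference
    implementation, and generators for synthetic networks and expression
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    boot,
    limma,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
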