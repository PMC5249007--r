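Package: antimedian
Title: Breakpoint Anti-Median Construction for Signed Circular Genomes
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for gene-order comparison under the breakpoint distance
    and for constructing the breakpoint anti-median of three signed circular
    genomes: a compatible-adjacency sampling scheme that includes every
    adjacency shared by two or three of the inputs, samples prescribed
    proportions from each genome's exclusive adjacencies, greedily maximizes
    the third proportion, and completes the result to a full genome by a
    uniform random matching of the remaining gene ends.  Includes closed-form
    expectations for the maximal third proportion and for the normalized
    breakpoint-distance score, a seeded generator of genome trios with an
    exactly prescribed overlap structure, GRIMM-style gene-order file I/O,
    and a command-line interface for reproducible simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
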