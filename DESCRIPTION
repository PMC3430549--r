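Package: syntenyviz
Title: Multi-Genome Synteny Visualization, Filtering and Track Ordering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Read, validate, filter and render multi-genome synteny data.
    Implements an open-ended tab-delimited interchange format for conserved
    region pairs and genome annotations (with transparent gzip/zip
    decompression), converters from BLAST tabular, axt and GFF3 outputs,
    numeric filtering of conserved regions, greedy genome-display-order
    optimization for pairwise and multiple viewing modes with an exhaustive
    oracle, deterministic SVG rendering of pairwise, multiple and circular
    overview displays, a seeded synthetic-data generator, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
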