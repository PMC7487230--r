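Package: cowordnet
Title: Concept Co-Occurrence Networks for Literature Mapping
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for co-word analysis of bibliographic corpora: parse Web of
    Science tab-delimited exports, tag articles against a hierarchical concept
    scheme (parent and child nodes with curated keyword assignments), build
    symmetric co-occurrence count matrices, compute keyword-normalized
    connectivity networks with weighted degrees and median-threshold
    sub-networks, and export deterministic circular-layout graphs as GEXF or
    GraphML for viewers such as Gephi. Includes a seeded synthetic-corpus
    generator with planted concept co-memberships and ground truth, so every
    pipeline stage is testable without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
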