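Package: gmsalayout
Title: Layered Layouts for Genome-Wide Multiple Sequence Alignment Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Draws genome-wide multiple sequence alignment (gMSA) graphs as
    layered, guide-anchored diagrams for the visual comparison of genome
    orders. Vertices are (merged) alignment blocks and each contig's traversal
    over the blocks is a vertex sequence; the first sequence is the guide, the
    rest are comparative sequences anchored on it. The layout pipeline extends
    the Sugiyama framework with a bypath-based cycle removal that keeps the
    guide's first and last blocks as the unique source and sink, longest-path
    layering with dummy-vertex properization, crossing reduction by global
    sifting of whole block-sets, greedy vertical track stacking, orthogonal
    routing of bundled multi-edges, and SVG rendering with directional and
    start/end glyphs. A seeded synthetic-graph generator, a native JSON/TSV
    dialect and a MAF reader make the whole pipeline testable offline.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
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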