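Package: leafdeck
Title: Leaf Decks and Reconstruction Counter-Examples for Unrooted
    Phylogenetic Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Machinery for studying leaf-reconstruction of unrooted
    phylogenetic networks: partially labelled multigraphs with leaf removal
    (vertex deletion followed by degree-2 suppression), X-decks, exact
    witnessed multigraph isomorphism testing, and generators for two
    parameterised families of networks (a non-binary family built on
    parity classes of binary sequences and a binary family built from
    caterpillars and lexicographic trees) that have identical decks yet
    are not isomorphic.  Includes certificates of non-equivalence based on
    leaf-distance profiles, a plain-text edge-list format with GraphML
    export, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
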