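Package: formcompare
Title: Semantic Comparison of Concept-Annotated Clinical Study Forms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Automated comparison of medical documentation forms stored as
    CDISC ODM 1.3 study metadata with concept-code annotations (for example
    UMLS Concept Unique Identifiers attached via ODM Alias elements). Item
    pairs are classified as identical, matching, similar or differing based
    on item name, concept code and value domain; two forms are aligned by a
    best-fit one-to-one item matching and summarised in an aggregated
    report. Sets of forms are compared pairwise into count matrices,
    normalised, converted to distances and clustered hierarchically.
    Includes red-to-yellow grid-image heatmaps, dendrogram plots, Newick
    tree export, a synthetic ODM form generator with planted overlap
    structure for validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    rlang,
    stats,
    stringi,
    tibble,
    tools,
    utils,
    xml2
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
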