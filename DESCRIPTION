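Package: admod
Title: Disease-Module Construction and Node-Depletion Analysis of
    Protein Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds disease modules from evidence-filtered protein-protein
    interaction data (PSI-MITAB 2.5, STRING-like and BioGRID-like tabular
    exports), overlays an experimentally supported miRNA-target regulatory
    layer, computes degree, betweenness and closeness centralities, performs
    in silico single-node depletion scans to rank candidate targets for
    miRNA-mimic therapeutics, and tests disease-gene enrichment with an
    exact conditional test. Includes a seeded synthetic-interactome
    generator with planted bridges, pendant chains and a planted
    enrichment odds ratio, so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
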