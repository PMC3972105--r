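Package: hubmir
Title: Hub microRNA Discovery from Expression and Regulation Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A system-level pipeline for identifying hub microRNAs (miRs)
    in a two-group microarray study. Implements two-class Significance
    Analysis of Microarrays (SAM) with permutation-based false discovery
    rate control, hypergeometric overlap testing against a curated
    disease-miR list, consensus filtering of predicted miR targets,
    offline over-representation analysis against GMT annotation sets,
    tripartite transcription-factor to miR to mRNA regulatory networks
    scored by intermediate regulation (in-degree times out-degree),
    Pearson co-expression networks with topological hub statistics
    (degree, betweenness, eccentricity, clustering coefficient), and
    agglomerative clustering under correlation distance. A synthetic-data
    generator emulates every required input so the whole pipeline runs
    and is verified offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
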