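Package: somscape
Title: Self-Organizing Map Portraits for Time-Course Presence/Absence Proteomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of weekly presence/absence proteomics cohorts
    with self-organizing map (SOM) expression portraits. Builds mean-volunteer
    detection-fraction matrices from binary per-volunteer tables, trains a
    40x40 batch SOM, segments the map into co-expression spot modules
    (percentile, correlation and k-means methods), projects samples into
    similarity space (second-level SOM and ICA) to draw time trajectories,
    scores spot-spot association with weighted topological overlap, tests
    module coherence with a beta statistic, performs gene-set enrichment
    (Fisher and GSZ), propagates pathway signal flow over signed KEGG-style
    graphs, and tracks total-abundance variance over time. Includes a
    synthetic-cohort generator with planted wave-like co-expression modules
    so every stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    grid,
    jsonlite,
    xml2,
    igraph,
    generics,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
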