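Package: chilltraj
Title: Trajectory-Centric Analysis of Chilling-Requirement Divergence in
    Stage-Resolved Bud Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for dissecting cultivar-specific chilling requirement (CR)
    from stage-resolved bud transcriptomes and matched hormone measurements.
    Implements intra-cultivar z-score standardization of temporal expression
    trajectories and their partition into k-means trajectory modules,
    stage-resolved High-CR versus Low-CR divergence statistics with
    discordance, cross-cultivar concordance and abundance filters,
    hypergeometric term enrichment with Benjamini-Hochberg FDR control,
    stage-residualized co-expression networks with a compact WGCNA-style
    module layer (topological overlap, eigengenes, module-trait models),
    cross-cultivar consensus edge filtering, and an integrated evidence score
    that ranks candidate regulators. A synthetic-data generator with planted
    trajectory archetypes, CR offsets, hormone coupling and enriched terms
    makes every stage of the pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
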