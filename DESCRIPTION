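Package: somEnrich
Title: Self-Organizing Map Clustering of Bioassay Activity Profiles with
    Gene-Target Enrichment for Drug Repurposing
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Clusters compounds by quantitative high-throughput screening
    (qHTS) activity profiles with a self-organizing map, consolidates
    undersized clusters by complete-linkage hierarchical merging of cluster
    centroids under Pearson distance, joins compounds to gene-target
    annotations through salt- and stereo-insensitive InChIKey block-1 keys,
    detects per-cluster gene-target and pathway overrepresentation with
    one-tailed Fisher exact tests under beta-uniform-mixture false discovery
    rate control, and validates cluster structural coherence with Tanimoto
    fingerprint similarity. Ships a seeded synthetic-data generator with
    planted ground truth so the whole pipeline is testable without external
    screening data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    withr,
    ChemmineR,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
biocViews: Cheminformatics, Clustering, Pathways, MultipleComparison
Config/testthat/edition: 3
RoxygenNote: 7.3.3
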