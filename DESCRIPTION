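Package: oudpath
Title: Multi-Stage Survival Modelling of Opioid Use Disorder Trajectories
    and Evidence-Weighted Therapy Knowledge Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models the three clinical transitions of opioid use disorder
    (onset, remission, relapse) from longitudinal coded-concept event
    streams.  Builds counting-process (start-stop) person-period data with
    time-indexed features (windowed counts, cumulative exposure, recency),
    fits L1-penalized Cox proportional-hazards models per data shard with
    cross-validated penalty selection, and aggregates selection frequencies
    and hazard ratios across shards to prioritize stable predictors.  A
    companion module builds an evidence-weighted disease-gene-pathway-drug
    knowledge graph from GWAS-style gene evidence, pathway membership (GMT)
    and gene-drug target tables, and ranks candidate drugs by Personalized
    PageRank.  Includes a seeded synthetic-data generator with planted
    hazard effects so the whole pipeline is testable without access to
    protected health data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    glmnet,
    survival,
    fgsea,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
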