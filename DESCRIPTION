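Package: ddpred
Title: Drug-Disease Association Prediction from Meta-Path Neighbor
    Topologies and Pairwise Node Attributes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts disease indications for drugs by link prediction over
    three drug-disease heterogeneous networks built from chemical-substructure,
    protein-domain and gene-ontology drug similarities plus a DAG-based disease
    semantic similarity.  Two learned branches score each drug-disease pair: a
    topology branch that aggregates multi-scale meta-path neighbor sets with
    neighbor-scale-level and neighbor-topology-level attention and encodes the
    pair with a small convolutional network, and an attribute branch that
    embeds the pair's rows of the three networks and encodes them with a
    convolutional autoencoder.  Includes a seeded synthetic-data generator with
    planted low-rank association structure, per-drug cross-validation with
    AUC/AUPR/top-k recall, and ranked export of novel disease candidates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
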