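Package: ezmetric
Title: Weighted Embryonic Zebrafish (EZ) Metric Nanotoxicity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for multi-endpoint developmental toxicity screening with
    embryonic zebrafish. Computes the weighted EZ Metric score over 21
    mortality and sub-lethal endpoints per exposure concentration, estimates
    effect concentrations (EC50 and EC at score 0.1) by linear interpolation
    on log concentration, builds hazard rankings, clusters
    concentration-response profiles with Ward linkage and classifies cluster
    membership from surface functional groups with a gain-ratio decision
    tree, and fits an exponential response-surface model of gold-nanoparticle
    toxicity from surface-ligand descriptors. Includes a synthetic 96-well
    plate-data generator with Hill-curve dose-response endpoints for
    validation and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    ape
Suggests:
    testthat (>= 3.0.0),
    mclust,
    minpack.lm,
    optparse,
    rpart,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
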