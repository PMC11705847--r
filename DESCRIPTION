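Package: phyllonet
Title: Diversity, Co-Occurrence Networks and Community Assembly for
    Phyllosphere Mycobiomes
Version: 1.0.0
Authors@R:
    person("Phyllonet", "Developers", email = "phyllonet@example.org",
           role = c("aut", "cre"))
Description: Tools for the community-ecology inference chain used in
    phyllosphere (leaf-surface and leaf-interior) fungal microbiome studies:
    OTU table import, abundance filtering and rarefaction; alpha diversity,
    robust Aitchison (rclr) distances, principal coordinates analysis,
    PERMANOVA, SIMPER decomposition and Levins niche breadth; thresholded
    Spearman co-occurrence networks with modularity, Zi-Pi connectivity and
    keystone-role classification; the Sloan neutral community model with
    bootstrap confidence intervals and prediction-band partitioning; and
    phylogenetic null models (beta-MNTD, beta-NTI, Raup-Crick on Bray-Curtis,
    pNST) that partition community assembly into heterogeneous selection,
    homogeneous selection, dispersal limitation, homogenizing dispersal and
    drift.  Includes generative simulators (neutral Sloan sampling, selection
    along an environmental gradient, dispersal-limited drift, planted modular
    correlation blocks) so that every estimator ships with a
    parameter-recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    vegan,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    biomformat,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
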