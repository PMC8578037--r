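Package: scovnet
Title: Structural Covariance Network Analysis of Subcortical Morphometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds group-level structural covariance networks (SCNs) from
    regional gray-matter volumes and compares their graph-theoretic topology
    between groups. Regional volumes are adjusted for age and intracranial
    volume, correlated across participants into a Pearson association matrix,
    and binarized over a network-density sweep. Global (clustering,
    characteristic path length, global efficiency, normalized small-world
    indices, modularity) and nodal (degree, clustering, betweenness)
    properties are computed per density, compared between groups with
    permutation tests and an across-density functional (area-between-curves)
    statistic, and characterized by exponentially truncated power-law degree
    fits and random-failure resilience curves. A volumetric arm provides
    MANCOVA, per-region ANCOVA with FDR and pairwise post-hoc contrasts,
    demographic tests, and region-psychometric correlations. A synthetic
    cohort generator with latent-factor covariance structure supports testing
    and calibration without access to participant-level imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
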