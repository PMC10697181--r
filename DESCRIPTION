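Package: wbnet
Title: Weighted Structural Brain Network Construction and Topology
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds weighted structural connectomes from streamline-level
    tractography tables (streamline count, mean length, SIFT2 weight sums,
    length-weighted COMMIT weight sums, and tractometry metrics such as R1,
    FA, RD and ICVF), applies streamline- and edge-level COMMIT filtering
    and group-consensus masking, and characterizes the resulting networks:
    quartile-dispersion edge-weight variability, edge-length-binned and
    residualized edgewise correlations with permutation tests, and
    null-model-normalized topology (small-worldness, weighted rich-club
    curves and hubness scores) against degree- and strength-preserving
    surrogates generated by Maslov-Sneppen rewiring and simulated
    annealing. A synthetic-cohort generator with configurable
    weight-length, weight-function and weight-myelin couplings supports
    fully reproducible end-to-end runs without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    Matrix,
    data.table,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
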