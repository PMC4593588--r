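Package: cloneTree
Title: Subclonal Phylogeny Reconstruction from Multi-Sample Tumor Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Infers the clonal evolutionary history of a tumor from variant
    read counts observed across multiple samples of the same patient. A
    generalized likelihood ratio test with a conservative chi-square mixture
    null decides, for every ordered pair of mutations or mutation clusters,
    whether one can precede the other in a lineage; the rejected pairs form
    precedence-order-violation matrices that, together with a mass
    (cellularity conservation) cost, score candidate subclone trees. A
    genetic algorithm searches the space of labeled rooted tree topologies
    for the maximum-fitness phylogeny. Also includes a naive
    read-count-to-cellularity estimator, exhaustive topology enumeration for
    small trees, and a simulation harness that generates synthetic
    multi-sample tumor sequencing data from known subclone trees for power
    and reconstruction benchmarks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
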