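Package: quantconn
Title: Quantitative Structural and Functional Brain Connectome Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of quantitative brain connectomes:
    microstructure-informed streamline weighting via a ball-and-stick
    signal decomposition solved with non-negative least squares,
    construction of structural (tractography-derived) and functional
    (BOLD-correlation) connectivity matrices with prevalence and
    proportional-density thresholding, weighted global graph metrics
    (density, mean strength, global efficiency, clustering, Newman
    spectral modularity), network-based statistics with permutation-based
    family-wise error control, healthy-control-referenced z-score
    disruption indices, and moderated regression linking structural
    disruption and functional deviation to cognitive scores. Includes a
    synthetic cohort generator with planted group effects for validation
    at toy scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    pracma,
    sandwich,
    lmtest,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
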