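Package: hingeshift
Title: Perturbation-Response Flexibility and Coupling Analysis for
    Hinge-Shift Protein Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Residue-level conformational dynamics analysis from elastic
    network models or coordinate ensembles. Implements perturbation
    response scanning (PRS) on anisotropic-network or ensemble-derived
    covariance matrices, the dynamic flexibility index (DFI) and dynamic
    coupling index (DCI) with percentile ranking, windowed covariance
    estimation with convergence diagnostics, hinge classification across
    an ancestor/descendant protein pair, selection of hinge-shift and
    allosteric (DARC-spot) mutation sets, and SVD-based clustering of
    flexibility profiles. Includes deterministic synthetic fixtures
    (toy structures, ground-truth covariances, Gaussian ensembles) so
    the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    yaml,
    ape,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0),
    MASS,
    optparse
Config/testthat/edition: 3
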