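Package: ensdiff
Title: Comparison of Bound and Unbound Protein Conformational Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts geometric descriptors (inter-region distances, radius of
    gyration, solvent accessible surface area, per-residue fluctuation, and
    hydrogen-bond counts) from multi-replica molecular-dynamics ensembles of a
    receptor simulated in two conditions (ligand-bound versus free), and
    quantifies per-region differences with a mean difference d, a
    range-normalised d/r, and the total variation distance between the pooled
    descriptor distributions.  Significance is assessed by replica-level
    resampling; summary tables mask values outside the top or bottom 5% of the
    resampling null.  Includes hydrogen-bond network difference maps, a
    replica-variance bootstrap, and synthetic ensemble generators so the whole
    pipeline is testable without running molecular dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
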