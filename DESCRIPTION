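Package: emtspectrum
Title: Multiphasic Epithelial-Mesenchymal Spectrum Analysis of Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps bulk or single-cell transcriptomes onto a two-dimensional
    epithelial (E) - mesenchymal (M) score space with a single-sample
    Kolmogorov-Smirnov random-walk enrichment statistic, infers EMT
    subpopulations with diagonal-family Gaussian mixture models selected by
    BIC, reconstructs nonlinear EMT paths by segmented (breakpoint)
    regression in rotated progression/deviation coordinates, models
    TGF-beta induction time courses as triphasic piecewise-linear
    trajectories, subclusters E- and M-genes by regulatory circuit with a
    semi-supervised self-organizing map, and compares clusters with Welch
    tests, Benjamini-Hochberg correction, and chi-squared enrichment.
    Includes seeded synthetic-data generators emulating the statistical
    structure each stage assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    mclust,
    yaml,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
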