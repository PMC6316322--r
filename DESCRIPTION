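Package: groveniche
Title: Presence-Only Climatic Niche Models for Aggregated Overwintering Sites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maximum-entropy (Maxent-style) presence-only species distribution
    modelling for clustered occurrence records such as monarch butterfly
    overwintering groves. Provides an L1-regularized maximum-entropy model
    fitted by coordinate descent with logistic output, AICc-based optimization
    of the regularization multiplier (coarse integer sweep, 0.1-step
    bracketing, and a final 0.1-2.0 scan), two correlation- and
    contribution-based variable-elimination procedures, projection of fitted
    models onto altered (future-climate) raster stacks with clamping and
    distribution-shift diagnostics, ESRI ASCII grid input/output, systematic
    thinning of grove-level occurrence records, and a seeded synthetic-data
    generator (elevation-coupled monthly climate layers, clustered grove
    occurrences, scenario deltas) so the whole pipeline runs without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
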