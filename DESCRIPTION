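Package: bsmap
Title: Statistical Parametric Mapping of Bodily Sensation Drawings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Toolkit for group-level analysis of bodily sensation maps:
    free drawings of perceived sensations on a two-view human body template,
    collected per subject and session. Provides per-session unit-range
    normalization, baseline-map subtraction, mask-restricted pixel-wise
    one-sample and paired t-statistics with t-to-Z transformation,
    Monte-Carlo cluster-extent correction for multiple comparisons
    (simulated smooth Gaussian null fields, maximum-cluster-size null
    distribution, extent threshold at a corrected family-wise alpha),
    factorial analysis of 13-item needling-sensation questionnaires, a
    synthetic-study generator with planted ground-truth effects, and
    rendering of Z-score topographies on the body outline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    grDevices,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
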