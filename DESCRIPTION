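Package: mirtriad
Title: miRNA Panel Screening by Pooled 2^-ddCT Quantification and Triple-Differential Calling
Version: 0.1.0
Authors@R: person("Analysis", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for TaqMan low-density-array style miRNA screening of small
    patient cohorts: reading and writing cycle-threshold (CT) tables with explicit
    non-detected ("Undetermined") semantics, detection filtering (strict CT cutoff),
    housekeeper normalization and the 2^-ddCT relative-quantification chain,
    strict fold-change calling across pairwise group contrasts, direction-agnostic
    triple-differential intersection, candidate annotation against a user-supplied
    disease-association table, and cohort-level inference with two-sided Fisher
    exact tests and Student's t-tests. A synthetic CT-data generator emulates a
    754-target + 4-control panel with physical pooling, planted log2 fold changes,
    Gaussian CT noise and a detection ceiling, so the full pipeline is testable
    without instrument exports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
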