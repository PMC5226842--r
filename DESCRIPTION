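Package: svexchange
Title: Generalized Single-Variable-Exchange Samplers for Item Response Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Posterior simulation for person parameters in exponential-family
    item response models (Rasch and two-parameter logistic) by the
    Single-Variable-Exchange (SVE) algorithm and its generalizations:
    oversampling of proposals, rank-matching of proposals to multiple
    targets, recycling rejection sampling for pooled discrete scores,
    statistic binning for weighted scores, and augmented-variable proposals.
    Includes chain diagnostics (acceptance and direct-hit rates,
    autocorrelation, effective sample size, mixing distributions), synthetic
    data generation, and experiment drivers for the reference scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, graphics, utils
Suggests: testthat (>= 3.0.0), optparse, jsonlite
Config/testthat/edition: 3
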