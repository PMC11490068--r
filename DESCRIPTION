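Package: doubleread
Title: Latent-Trait Reader Models and Pairing Strategies for Double-Read
    Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models binary recall decisions of screening-mammography readers
    with a latent-trait logistic model (fixed per-reader effects on the logit
    scale plus a shared normal case random effect), fits it by maximum
    likelihood from per-reader and per-pair binomial counts using Monte Carlo
    marginalization and Powell's derivative-free method, and simulates
    year-long double-reading programmes to compare seven reader-pairing
    strategies (similar, opposite, and random pairing on true-positive rate,
    false-positive rate, or a composite score) with bootstrap confidence
    intervals. Includes a synthetic-data generator reproducing the structure
    of double-read screening registries.
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
    pracma,
    optparse
Config/testthat/edition: 3
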