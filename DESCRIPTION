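Package: nbstates
Title: Narrative Semantics and Dynamic Brain States in Naturalistic fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links the semantic content of a movie narrative to dynamic
    brain states estimated from naturalistic fMRI. Timed subtitle text is
    tokenized, binned to the scanner's repetition-time grid, smoothed,
    tf-idf weighted and factored by nonnegative matrix factorization into
    semantic contexts. Per-subject multivariate-Gaussian hidden Markov
    models segment region-network time series into recurring brain states;
    correlation-based link statistics with permutation nulls, dwell-time
    dynamics and group-level state-aligned partial-least-squares
    signatures quantify how brain states track the story. A synthetic-data
    generator with known ground truth makes every stage testable at desk
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
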