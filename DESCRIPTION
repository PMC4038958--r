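Package: scoremiv
Title: Score-Based Measurement Invariance Tests for Factor Analysis Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Maximum likelihood estimation of multiple-group confirmatory
    factor analysis models with cross-group equality constraints, and
    score-based tests of measurement invariance (parameter instability)
    with respect to continuous, ordinal, and categorical auxiliary
    variables. Provides casewise score matrices, observed/expected/
    outer-product information, decorrelated cumulative score (empirical
    fluctuation) processes, the double-maximum, Cramer-von Mises, maximum
    Lagrange multiplier, weighted ordinal double-maximum, ordinal maximum
    Lagrange multiplier and unordered Lagrange multiplier statistics with
    analytic or simulated null distributions, instability plots, and
    Monte-Carlo engines for size and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, grDevices, tools, jsonlite
Suggests: testthat (>= 3.0.0), optparse, sandwich
Config/testthat/edition: 3
RoxygenNote: 7.3.3
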