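Package: eqgof
Title: Equivalence Testing for Goodness-of-Fit of Continuous Distributions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tests that establish, rather than refute, the fit of a
    hypothesized continuous distribution. The indifference zone around the
    model F0 consists of Lehmann alternatives F0^theta with the hazard-ratio
    type parameter theta confined to a multiplicative interval
    (1/(1+eps), 1+eps); rejecting the null hypothesis of relevant model
    deviation establishes goodness-of-fit at level alpha. Provides the
    conversion between the Kolmogorov-distance margin delta and the Lehmann
    margin eps, the exact uniformly most powerful test with its chi-square
    distribution theory (critical constants, power, sample size), a
    grouped-data multinomial equivalence counterpart based on the Euclidean
    distance between class-probability vectors, and a double one-sided
    (TOST) score test for location-scale families with unknown location and
    scale, using expected-information variance estimates obtained by
    quadrature. A command-line interface exposes all procedures.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    optparse,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
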