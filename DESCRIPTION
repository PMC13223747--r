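Package: mplselect
Title: Selection Inference from Allele-Frequency Time Series under
    Limited Sampling and Genetic Drift
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Closed-form estimation of single-locus selection coefficients
    from temporal allele-frequency data using the marginal path likelihood
    (MPL) approximation of the Wright-Fisher process, with a bias
    correction for finite-sample (binomial) observation noise. Includes
    Wright-Fisher and deterministic simulators, analytical performance
    theory (estimator mean, exact sampling-noise moment formulas, variance
    decomposition into sampling-only and drift-only components, the
    Cramer-Rao lower bound 1/(N*V), Gaussian approximation, and the
    minimum detectable selection coefficient), likelihood-ratio confidence
    intervals, a grid-discretised hidden Markov model benchmark estimator
    with binomial emissions, and a Monte-Carlo harness that validates the
    theory against simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
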