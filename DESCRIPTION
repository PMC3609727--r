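Package: radrate
Title: Clade Dating and Diversification Rates for Rapid Radiations
Version: 0.1.0
Authors@R:
    person("radrate", "maintainers", email = "radrate@example.org",
           role = c("aut", "cre"))
Description: Tools for dating clades and measuring their diversification
    from a single-locus phylogram: penalized-likelihood rate smoothing
    under a fixed (secondary) root calibration, linear propagation of
    calibration uncertainty to clade-age confidence intervals, Nei's
    nucleotide diversity with its variance under pairwise deletion,
    Magallon-Sanderson crown-group net diversification rates under
    minimal and maximal species-number scenarios, and sampled-fraction
    species extrapolation. Includes seeded birth-death tree simulation,
    autocorrelated lognormal branch rates and Jukes-Cantor sequence
    simulation so the whole pipeline is testable against known truth,
    plus a command-line entry point producing a per-clade report table.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
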