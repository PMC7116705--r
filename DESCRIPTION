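Package: mcp2
Title: Multiple Change Point Detection and Validation in Autoregressive
    Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects and validates multiple change points in piecewise
    stationary autoregressive time series. Likelihood-ratio scan statistics
    over sliding windows propose candidate change points; a parametric
    spectral discrimination likelihood-ratio test on adjacent segments,
    built on Yule-Walker estimation via the Levinson-Durbin recursion,
    assigns each candidate a p-value; Benjamini-Hochberg or Bonferroni
    (Wright) multiple-testing procedures prune the candidates to the final
    change point set. Includes a piecewise AR/ARMA simulator with a library
    of nine benchmark models and a Monte Carlo harness reporting exact
    detection rates and change point location errors.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
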