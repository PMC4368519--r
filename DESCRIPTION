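Package: sadpower
Title: Power Analysis for Neutrality Tests on Species Abundance Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify how detectable non-neutral community processes
    are from species abundance distributions. Provides stochastic simulators
    for three non-neutral local community models (density-dependent mortality,
    Ricker-like fecundity competition, and intrinsic fitness differences)
    coupled by immigration to logseries or perfectly even metacommunities; the
    exact sampling-formula likelihood of Hubbell's standard neutral model and
    its maximization over the immigration and biodiversity parameters; a
    parametric-bootstrap test of the neutral null hypothesis; statistical
    power estimation with Jeffreys binomial confidence intervals; and matching
    of model parameters to empirical species richness and Shannon diversity.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
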