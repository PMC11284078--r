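Package: swmcann
Title: Sequential Working Memory in a Continuous Attractor Network with
    Short-Term Plasticity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a ring attractor network of rate neurons with
    Tsodyks-Markram short-term facilitation and depression, together with the
    delay-recall task used to study serial position effects in sequential
    working memory.  Provides the task protocol (sequential item encoding,
    maintenance, cued recall), population-vector decoding of recall responses,
    recall statistics (normalized target probability via von Mises mixture
    fits, circular variance and kurtosis), a reduced closed-form theory of the
    primacy-to-recency transition, and reproducible experiment drivers with
    parameter sweeps and run manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
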