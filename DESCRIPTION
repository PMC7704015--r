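Package: dallaltest
Title: Homogeneity Tests for Intraclass Correlation in Bilateral Binary Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Inference for bilateral (paired-organ) binary response data
    under Dallal's model, in which the conditional probability of response
    at one organ given response at the other (gamma) is free of the marginal
    response rate (pi). Provides closed-form maximum likelihood estimates,
    three asymptotic tests (likelihood ratio, score, Wald-type) of
    homogeneity of gamma across groups, exact conditional and exact
    unconditional-maximization p-values built on the same statistics, full
    table-space enumeration, and a Monte Carlo engine for type I error and
    power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
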