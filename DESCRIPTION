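Package: phitime
Title: Integrated Information Measures for Stationary Multivariate Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Measures of integrated information for stationary multivariate
    time series and their generative multivariate autoregressive (MVAR)
    models: the empirical-distribution measure Phi-E, its
    stochastic-interaction variant, the regression-based Phi-AR, and a
    Gaussian extension of the discrete/Markovian measure Phi-DM. Stationary
    and lagged covariances are obtained analytically via the discrete-time
    Lyapunov equation or estimated from multi-trial recordings; integrated
    information is the effective information across the minimum information
    bipartition, located by exhaustive normalized search. Includes canonical
    network generators, simulation with Gaussian or exponential innovations,
    genetic-algorithm optimization of network topology for high integrated
    information, and landscape probes (single-mutation sensitivity,
    connection-strength sweeps).
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
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
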