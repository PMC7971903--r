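Package: pibop
Title: Predictive Information Bottleneck for Optimal Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Solvers and analyses for optimal prediction under resource
    constraints using the information bottleneck. Implements the analytic
    Gaussian information bottleneck (spectrum, critical tradeoffs, optimal
    linear encoders, information curves) for jointly Gaussian past/future
    variables; closed-form results and transferability analysis for the
    stochastically driven damped harmonic oscillator; extended-history
    bottlenecks for generalized Langevin dynamics with power-law memory;
    a discrete Blahut-Arimoto bottleneck solver for Wright-Fisher
    allele-frequency dynamics; seeded trajectory simulators used as
    Monte-Carlo oracles; and a steady-state Kalman-filter baseline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
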