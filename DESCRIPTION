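Package: tissuecode
Title: Rule-Based Simulation of Tissue Renewal by Asymmetric Cell Division
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic simulators of epithelial tissue renewal driven by five
    rules for the timing, order, direction, number, and lifespan of cell
    divisions, as in colonic crypt self-renewal. Provides a non-spatial lineage
    model whose cell counts follow generalized Fibonacci p-number recurrences, a
    spatial rosette model with rotating division directions on a planar lattice
    (with a cylindrical projection that emulates the crypt wall), exact
    arbitrary-precision p-Fibonacci accounting, and a linear four-compartment
    continuous model with closed-form eigenvalues, steady-state ratios, and the
    discrete-to-continuous rate-constant correspondence. All outputs are tidy
    tibbles; results plot with autoplot() and summarize with tidy()/glance().
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    jsonlite,
    readr,
    deSolve,
    optparse,
    generics,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ape
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
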