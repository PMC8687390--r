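Package: ffde
Title: Fuzzy Fractional Differential Equation Solvers for Predator-Prey Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: One-step numerical solvers for coupled systems of fractional
    differential equations in the Caputo sense with fuzzy initial conditions.
    Implements the fractional Euler method and a midpoint-style fractional
    modified Euler method, propagates triangular and exponential fuzzy numbers
    through r-cut interval stepping, and ships the two fractional-order
    predator-prey model families they were designed for (a time-varying
    coefficient model and the non-dimensionalised Lotka-Volterra system),
    together with fractional-calculus oracles (Riemann-Liouville integral,
    Caputo derivative, generalised Taylor partial sums, Mittag-Leffler
    series), a convergence-order verification harness, deterministic TSV
    trajectory serialisation, and envelope/phase plotting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
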