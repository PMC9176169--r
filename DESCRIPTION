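Package: givestat
Title: Goodness of Instrumental Variable Estimates (GIVE) Statistic
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Goodness of fit for instrumental-variables (IV) regression.
    Implements the GIVE statistic, a coefficient-of-determination analogue
    for models estimated by two-stage feasible generalized least squares
    under non-spherical errors, together with classical grouping-instrument
    constructors (Wald median split, Durbin ranks, Bartlett terciles), the
    asymptotic standardized statistic, Monte-Carlo evaluation designs for
    multiple linear regression and structural measurement-error models, and
    a command-line interface for fitting, instrument comparison, and
    simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
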