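Package: delaynorm
Title: Delayed Divisive Normalization Models of Neuronal Temporal Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Forward modeling and estimation of time-varying neural responses
    to arbitrary contrast time courses with a Linear-Nonlinear-Gain-control
    model in which the divisive gain signal is a delayed (low-pass filtered)
    copy of the driving signal. Includes comparison models (compressive
    temporal summation and a two-temporal-channels model), grid-plus-simplex
    parameter estimation with bootstrap and leave-one-out resampling,
    broadband high-frequency envelope extraction from raw voltage epochs,
    BOLD amplitude prediction for one- and two-pulse temporal conditions,
    and synthetic data generators for all of the above.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
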