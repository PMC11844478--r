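Package: rgshape
Title: Shape of a Bivariate Genetic Relationship from Bin-Pair Genetic
    Correlations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers the shape of a possibly nonlinear relationship between
    the additive genetic components of two traits from genetic correlations
    between quantile bin-pair contrast GWASs of a continuous trait and a
    second trait. Each bin-pair genetic correlation is converted to an acute
    angle and then, via the tangent, to a distance on the second trait's
    liability scale; the set of paired distances is reconstructed into a
    curve by equality-constrained cubic-spline (or fifth-degree polynomial)
    least squares. Includes resampling-based uncertainty envelopes and a
    polygenic two-trait simulator with configurable (non)linear genetic
    couplings for end-to-end validation.
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
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
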