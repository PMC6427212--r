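Package: relkin
Title: Drug-Release Kinetics: Model Fitting, Selection and Diffusion Theory
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Fits the standard family of drug-release kinetic models (zero
    order, Noyes-Whitney first order, Higuchi square-root, Siepmann-Peppas
    power law, Weibull) to cumulative-release profiles by weighted least
    squares, in both linearized and direct nonlinear form, and scores the
    competing fits with the Akaike, Schwarz and Imbimbo criteria and
    extra-sum-of-squares F-tests over a registry of nested model pairs.
    Includes the diffusion-theoretic square-root laws (error-function
    solution of Fick's second law for an infinite reservoir), release-profile
    normalization to an operational m-infinity, fitting-window and lag-time
    conventions, slope-parallelism tests across formulations,
    entrapment-efficiency and UV-calibration arithmetic, and a synthetic
    release-data generator for end-to-end validation.
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
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
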