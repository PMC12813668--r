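Package: flightscope
Title: Flight Performance Analysis for Ornithodolite Bird Tracks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the flight performance of large waterbirds
    such as great cormorants from ornithodolite (rangefinder-theodolite)
    observations. Implements the fixed-wing power-curve model of bird flight
    with its characteristic speeds (minimum power, maximum range, best glide)
    and muscle-power-limited maximum level speed; a logarithmic surface-layer
    wind model blended with balloon-sounded upper-air profiles; wind-triangle
    reconstruction of airspeed and heading from tracked positions; circular
    statistics including the Rayleigh and Watson-Williams tests and a
    wind-drift compensation index; a nested linear-model pipeline for
    airspeed with backward elimination and Tukey contrasts; and a synthetic
    ornithodolite session generator with known ground truth for validating
    every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    emmeans,
    stats,
    utils,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
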