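Package: impulsefire
Title: Lightning Impulse-Current Ignition Modelling for Conifer Needle Beds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling ignition of conifer needle fuel beds by the
    impulse-current component of a lightning strike. Synthesizes standard surge
    current waveforms (8/20 and 10/350 microsecond shapes) and extracts their
    timing and energy metrics; evaluates an energy-balance ignition criterion
    combining impulse-current heating, a heating-efficiency power law, and
    long-continuing-current energy; re-derives the power-law models by
    log-linear least squares; simulates staircase critical-ignition and
    breakdown-voltage protocols against stochastic oracles; and generates
    synthetic factorial experiment tables with the statistical structure the
    analysis assumes.
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
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
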