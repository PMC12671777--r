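Package: aquabatch
Title: Batch Processing, Visualization and Analysis of AquaCrop Simulation Outputs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A headless workflow for outputs of the FAO AquaCrop crop-water
    productivity model: discovery and matching of output files from batches of
    simulation runs (standard GUI and stand-alone plug-in modes),
    underscore-delimited filename metadata extraction, assembly into tidy
    project/seasonal/daily tables, time-window summary statistics
    (mean, SD, CV), grouped simple linear regression, and scatter/box plotting
    with a LOESS smoother. Includes a seeded synthetic fixture generator -- a
    toy crop-water simulator built on the canonical biomass-transpiration and
    yield-harvest-index relations (B = WP* x sum(Tr); Y = HI x B) with growing
    degree-day phenology and a 9-30 degree C temperature-stress rule -- that
    writes syntactically valid output file sets, so the whole pipeline can be
    exercised and tested without the AquaCrop engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    yaml,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
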