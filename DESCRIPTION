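Package: polexchange
Title: Single-Molecule Analysis of DNA Polymerase Exchange at the Replisome
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis tools for single-molecule studies of
    concentration-dependent DNA polymerase III* exchange at the E. coli
    replisome. Provides an event-driven multisite exchange simulator with
    photophysics (photobleaching, FRAP pulse schedules), kymograph rendering
    and fork tracking for rolling-circle replication assays, replication rate
    and processivity fitting, single-fluorophore calibration and
    integer-centered Gaussian mixture stoichiometry, single-molecule FRAP
    recovery-curve analysis with exchange-time estimation, two-color focus
    cross-correlation with mechanism classification, and photobleaching
    change-point step counting for cellular copy-number and concentration
    estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    tiff,
    minpack.lm,
    mclust,
    readr,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
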