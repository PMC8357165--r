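Package: nftsws
Title: Corticothalamic Neural-Field Simulation of Slow-Wave Sleep Stimulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates slow-wave-sleep EEG-like activity with a four-population
    corticothalamic neural-field model (excitatory and inhibitory cortex,
    thalamic reticular and relay nuclei) on a periodic two-dimensional sheet,
    driven by spatially white noise plus localised sensory stimulation.
    Provides open-loop (periodic, Poisson) and closed-loop phase-locked
    stimulation protocols, steady-state and linear transfer-function
    analysis, slow-oscillation and sleep-spindle detection with
    co-occurrence matching, Morlet scalogram band-power indices, and the
    statistical comparisons used to rank stimulation protocols.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    tibble,
    dplyr,
    purrr,
    ggplot2,
    rlang,
    generics,
    jsonlite,
    yaml,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
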