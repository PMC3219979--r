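Package: icusedsim
Title: Patient-Level Simulation of ICU Sedation Strategies, Length of Stay
    and Costs
Version: 0.1.0
Author: Package Author
Maintainer: Package Author <maintainer@example.net>
Description: An hourly, eight-state semi-Markov micro-simulation of
    mechanically ventilated intensive-care patients under a
    remifentanil-based versus a conventional analgo-sedation regimen.
    Provides Weibull survival mathematics for time-dependent hourly
    transition probabilities, maximum-likelihood estimation of dwell-time
    distributions from right-censored individual-patient records with
    bootstrap uncertainty, micro-costing-based accumulation of sedation
    and ICU-day costs over simulated patient histories, probabilistic
    sensitivity analysis with correlated Weibull parameter draws, and a
    synthetic trial generator with known ground truth for end-to-end
    validation of the estimation pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ggplot2,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
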