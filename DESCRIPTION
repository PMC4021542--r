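Package: npcdecode
Title: Bayesian Population Decoding of Oculomotor Behavior from Spike Trains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates delayed-memory-saccade sessions on a Cartesian grid
    with Poisson-spiking model neurons, and decodes presaccade eye position,
    saccade direction and postsaccade eye position from population spike
    counts by Bayesian maximum-a-posteriori inference under leave-one-out
    cross-validation. Provides neuronal-population-code (NPC) accuracy with
    bootstrap uncertainty, sliding-window accuracy time courses with
    epoch-level root-mean-square summaries and onset/peak detection, and
    Recursive Neuronal Elimination for ranking neurons by their contribution
    to the population code.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
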