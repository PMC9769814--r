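Package: trichoflux
Title: Carbon-Flux Trade-Off Model for Trichodesmium Colony Formation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A coarse-grained carbon flux model comparing the metabolic
    performance of Trichodesmium colonies against free trichomes. Tracks a
    biomass-normalized carbon storage pool driven by carbon fixation,
    the carbon cost of nitrogen fixation, respiration, and optional external
    interaction terms acting on rates or on biomass. Provides forward-Euler
    integration with an exact closed-form oracle, closed-form break-even and
    crossover thresholds, seeded parameter sweeps reproducing the scenario
    experiments (fixed respiration, respiration ratios, respiration
    proportional to carbon fixation, external influence on rates and on
    biomass, and variable carbon-to-nitrogen fixation ratios), tidy result
    tables, and ggplot2 visualisations.
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
    readr,
    rlang,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
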