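Package: mycoflux
Title: Stable-Isotope Tracer Design and Accounting for Mushroom Culture
    Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Design and analysis of 13C/15N/D stable-isotope tracer
    experiments in cultivated fungi such as Agaricus bisporus. Converts
    between delta notation, isotope ratios and atom fractions against a
    configurable standards registry; computes tracer doses for a target
    enrichment by two-pool isotope mass balance; turns bulk-IRMS sample
    tables and a labelling plan into per-compartment excess atom fractions
    and percent-of-added-tracer recovery with closure by difference;
    partitions sink (pin/mushroom) enrichment across labelled substrate
    layers normalised by independently measured initial layer enrichments;
    analyses nanoSIMS ion-count images at single-cell resolution (plane
    accumulation, ROI totals, carbon-dimer-corrected isotope ratios,
    control-relative delta values and 2-SD enrichment classification); and
    ships seeded synthetic-experiment generators with known ground truth so
    every stage is verifiable by parameter recovery.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
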