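Package: oligoflux
Title: Aggregation Kinetics, Oligomer Flux and Single-Molecule Imaging
    Analysis for Amyloid Inhibitor Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tidyverse-style toolkit for screening aggregation inhibitors
    (such as designed single-domain antibodies) against amyloidogenic
    proteins like alpha-synuclein. Fits seeded thioflavin-T kinetic traces
    with a linear elongation model and a generalized logistic (Richards)
    model, derives the analytical flux of reactive oligomers and its summary
    statistics (peak height, area, peak time), fits saturation-binding
    titrations, performs reference subtraction for biolayer-interferometry
    traces, detects diffraction-limited spots in single-molecule pull-down
    TIRF stacks, computes morphometrics (length, area, eccentricity,
    circularity) of super-resolved aggregates from localization tables, and
    reports ANOVA-based comparisons against a control condition. Includes
    seeded synthetic-data generators for every input so the full pipeline is
    testable without instrument data.
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
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr
Suggests:
    jsonlite,
    multcomp,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
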