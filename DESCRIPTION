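Package: hydrofrac
Title: Hydrogen Isotope Fractionation Analysis for Plant Carbohydrates and
    n-Alkanes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reduces dual water-vapor equilibration measurements of plant
    carbohydrates to nonexchangeable delta-2H on the VSMOW scale, computes
    apparent autotrophic and heterotrophic hydrogen isotope fractionation
    factors and abundance-weighted n-alkane delta-2H, runs and inverts the
    two-pool Roden-Ehleringer cellulose isotope model, accounts for
    carbon-bound hydrogen atoms of glucose and n-alkanes by biochemical
    source, and generates synthetic datasets with the statistical structure
    of nitrogen-fertilization and starch-deficiency experiments so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
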