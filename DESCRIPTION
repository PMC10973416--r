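Package: n2oph
Title: Soil pH Control of Nitrous Oxide Emission Factors and Denitrifier
    Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reproducible pipeline for synthesising field measurements of
    fertiliser-induced nitrous oxide (N2O) emissions against soil pH.
    Computes N2O emission factors from paired fertilised/control plot
    emissions, harmonises soil pH measured in different media to a common
    water basis, bins observations into 0.1-unit pH increments with
    replicate-weighted means, and fits competing linear and quadratic
    responses selected by small-sample AICc, locating the pH at which the
    fitted hump-shaped response peaks. Companion tools cover denitrification
    functional-gene meta-analysis (nirK, nirS, nosZ clade I abundances and
    the (nirK+nirS)/nosZI ratio), closed-bottle headspace N2O flux
    calculation, potential denitrification activity from acetylene-block
    incubations, and the N2O/(N2O+N2) denitrification product ratio.
    Seed-controlled synthetic-data generators with known ground truth make
    every stage of the pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
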