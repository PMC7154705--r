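Package: craftr
Title: Long-Term Forest Carbon Accumulation Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annual-step simulation of carbon in forest biomass, litter and
    soil organic matter at regional to national scales over decadal to
    centennial horizons. Standing biomass follows a logistic relationship
    between net primary production and biomass density parameterised from
    forest production (yield) tables; litter and humus follow a multi-pool
    decay scheme with climate-dependent rates, historical litter raking and
    land-use mixing. Includes exhaustive grid-search calibration of
    time-varying growth parameters against inventory biomass stocks, additive
    LMDI decomposition of biomass-stock change into area, species-composition
    and density contributions, a synthetic-region generator with known ground
    truth, and ggplot2 visualisations with broom-style tidiers.
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
    readr,
    yaml,
    jsonlite,
    generics,
    ggplot2,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
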