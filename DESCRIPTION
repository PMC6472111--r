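Package: bmslca
Title: Cradle-to-Bottle Carbon Footprint of Powdered Breastmilk Substitutes
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A configuration-driven life-cycle assessment pipeline comparing
    the carbon footprint of producing and consuming powdered breastmilk
    substitutes (BMS) with the footprint of breastfeeding. Implements recipe
    modelling with Codex Alimentarius compliance checks, a dairy co-product
    mass balance with multi-level allocation (dry mass, fat plus protein,
    energy, economic value), cradle-to-gate and cradle-to-bottle footprint
    aggregation for country scenarios, a breastfeeding equivalence model based
    on maternal diets, Monte Carlo uncertainty propagation, one-at-a-time
    sensitivity analysis, and scenario switches for packaging, sterilisation,
    GWP characterisation, land-use change and micronutrient additions.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
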