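Package: numeraire
Title: Multi-Numeraire Appraisal of Health-Related Projects Over Time
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts per-period streams of health effects, health-care costs
    and consumption costs into net health, equivalent health-care-resource and
    equivalent consumption effects; discounts each numeraire at its matched,
    country-specific rate (Ramsey consumption rates, health time-preference
    rates, dual rates for ICER reporting, scenario-based declining term
    structures, catastrophic hazards and project risk premia); and aggregates
    country-specific net present values into a global net present value with
    extensive period-by-period reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
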