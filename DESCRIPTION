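Package: barnspace
Title: Space-Use and Site-Fidelity Analysis for Barn-Housed Dairy Cattle
Version: 0.1.0
Authors@R:
    person("Barn", "Space Maintainers", email = "maintainers@barnspace.invalid",
           role = c("aut", "cre"))
Description: Tools to analyse indoor real-time location system (RTLS)
    trajectories of barn-housed dairy cows. Provides trajectory cleaning and
    moving-average smoothing, daily grid-cell utilisation distributions with
    50%/95% isopleth core and full ranges, Bhattacharyya-coefficient site
    fidelity, exhaustive AICc model screening of space-use measures against
    lameness, parity and days in milk with regression diagnostics, and an
    AICc-selected logistic classifier of lameness status. Includes a
    semi-Markov synthetic herd simulator so the whole pipeline is testable
    without access to farm data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
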