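Package: reroutecost
Title: Costs and Survival Effects of Rerouting Cancer Diagnoses from
    Emergency Presentation to Primary-Care Referral
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates what rerouting a cancer diagnosis from emergency
    presentation (EP) to GP/two-week-wait referral costs and saves, for
    registry-like patient cohorts with right-censored monthly hospital
    costs.  Implements a censored-cost three-part estimator (per-interval
    probit death models combined with hurdle-gamma cost models for
    decedents and survivors), decomposes the route effect on cumulative
    cost into survival and intensity-of-resource-use channels, fits
    Weibull accelerated failure time survival models with restricted mean
    survival differences (years of life saved), assembles a referral
    economics ledger including non-conversion diagnostic costs, and
    scales per-patient ledgers to aggregate policy impact by benchmarking
    commissioning regions against their best-performing quintile.  Ships
    a synthetic cohort generator emulating confounded route assignment,
    route-dependent Weibull survival, staggered-entry administrative
    censoring, and U-shaped cost trajectories, so the whole pipeline is
    testable without access to restricted registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
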