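Package: hivtdabc
Title: Time-Driven Activity-Based Costing for HIV Service Delivery
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for time-driven activity-based costing (TDABC) of HIV
    services at health facilities. Converts annual resource costs and
    practical capacities into per-minute capacity cost rates, turns timed
    care-pathway steps into per-encounter cost breakdowns across four
    categories (human resources, space/equipment, indirects, consumables),
    classifies antiretroviral therapy clients as stable or unstable and
    annualises their costs, aggregates service-line summary tables
    (mean, SD, IQR, category shares), builds a household wealth asset
    index by principal component analysis, and fits fixed-effects
    regressions of service cost and provider-client time on client and
    facility characteristics. A seeded synthetic-data generator emulates
    a multi-facility field study for validation and planted-effect
    recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    rlang,
    sandwich,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
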