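Package: deltagb
Title: Derivation of Forest Aboveground Net Biomass Change Default Rates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates aboveground net biomass change (dAGB, Mg/ha/yr) default
    rates for tropical and subtropical natural forests from plot-level data.
    Chronosequence plots are fitted with a linear mixed-effects model of AGB on
    log stand age (random site intercepts and slopes) from which site-specific
    regrowth rates for younger (<=20 yr) and older (20-100 yr) secondary
    forests are derived; permanent-plot census series yield weighted mean
    change rates with bootstrap percentile confidence intervals for old-growth
    and managed/logged forests. Category-level (continent x ecozone x forest
    type) defaults are assembled IPCC Tier-1 style, with minimum-data rules,
    a donor-continent recommendation ladder and an IPCC-2006 fallback. A
    synthetic-data module generates datasets with known ground truth for
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
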