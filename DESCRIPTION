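Package: prodloss
Title: Productivity Costs of Premature Mortality via Microsimulation Matching
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates the productivity costs of premature mortality under the
    human capital approach. Decedent records are matched at random, within
    cells defined by age category, sex and socioeconomic quintile, to persons
    in a simulated life-course population panel; each match supplies a
    counterfactual lifespan from which years of life lost, full-time
    equivalent working years and the present value of lifetime income (PVLI)
    forgone are accumulated to a projection horizon. Matching is replicated
    with independent seeds and results are summarised as replicate means with
    percentile confidence intervals, stratified by age band, sex and cancer
    site (ICD-10 C00-C97). A synthetic-data module generates mortality
    datasets and population panels with the statistical structure the
    analysis assumes, so the full pipeline runs without restricted registry
    or census data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
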