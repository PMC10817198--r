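Package: cherisk
Title: Catastrophic Health Expenditure Risk from Out-of-Pocket Surgical Costs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the risk of catastrophic health expenditure (CHE) from
    out-of-pocket (OOP) payments for pediatric surgical care. Incomes within a
    country are represented by gamma distributions whose shape is set by the
    Gini index and whose scale is pegged to household expenditure per capita;
    wealth-quintile distributions share the shape with means at 0.1-0.9 times
    the national mean. CHE risk is the incomplete-gamma probability that an
    OOP payment exceeds a threshold share (default 10%) of income, evaluated
    under OOP-reduction scenarios (70/50/30/10% of baseline). Includes
    calibration of the income proxy against poverty headcount and FGT-1
    poverty-gap statistics, aggregation to World Bank income groups and WHO
    regions with standard errors, and a synthetic country-table generator
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
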