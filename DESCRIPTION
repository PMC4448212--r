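Package: smokepov
Title: Parental Smoking and Child Poverty from Survey Aggregates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates the contribution of parental tobacco smoking to
    relative child poverty in the UK from printed national survey
    aggregates. Implements modified-OECD income equivalisation and
    poverty thresholds, marital-status weighting of smoking prevalence,
    decomposition of child counts by family structure and income band,
    attribution of children to household smoker configurations, weekly
    tobacco expenditure profiles (licit and illicit, manufactured and
    hand-rolling), and counts of children drawn into effective poverty
    when tobacco spend is subtracted from household income. A household
    level Monte-Carlo microsimulation validates the closed-form
    aggregate pipeline bottom-up.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
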