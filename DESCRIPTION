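Package: wheatdyn
Title: Logistic Accumulation Dynamics and Yield Analysis for Winter Wheat
    Sowing-Date Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing sowing-date field trials of winter wheat.
    Fits the three-parameter logistic model W = Wmax/(1 + a*exp(-k*t)) to
    per-stem dry-matter and nitrogen accumulation, derives the closed-form
    characteristic values of the fast accumulation phase (onset, termination,
    duration, inflection time, maximum and mean rates), summarises weather
    series into thermal time and phenology statistics (growing degree days,
    wintering onset, filling temperature), computes sowing-date yield-loss
    statistics and mature-to-jointing ratio regressions with yield-threshold
    solving, and generates fully synthetic sowing-date experiments with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
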