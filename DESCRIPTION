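Package: metalrisk
Title: Multi-Source Oral Exposure and Non-Carcinogenic Risk Assessment for
    Children
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Deterministic and probabilistic assessment of children's oral
    exposure to metal(loid)s (Mn, Pb, Cr, Cd, As) through food, drinking
    water and incidental soil ingestion.  Computes average daily doses,
    hazard quotients, hazard indices and total hazard indices from
    concentration and exposure-factor tables; fits lognormal sampling
    distributions to published summary statistics (quartiles or
    median/mean pairs); propagates them through the dose model by Monte
    Carlo simulation; and generates calibrated synthetic study cohorts
    for reproducing cohort-level findings when per-child raw data are
    unavailable.  Includes the nonparametric toolbox (Mann-Whitney,
    Spearman, Kolmogorov-Smirnov) used for age-group comparisons.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    jsonlite,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
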