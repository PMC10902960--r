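Package: esvtrend
Title: Ecosystem Services Valuation and Trend Analysis for Mining Landscapes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Benefit-transfer valuation of annual land-use rasters into
    ecosystem services value (ESV) with socioeconomic dynamic adjustment
    (GDP-index deflation and a logistic willingness-to-pay coefficient
    driven by the Engel coefficient), per-pixel Theil-Sen and Mann-Kendall
    trend classification, segmented log-linear (joinpoint) regression with
    annual and average annual percentage change, and mining-impact versus
    control comparison via buffered sample points and Mann-Whitney U tests.
    Includes a seeded synthetic mining-landscape generator so the whole
    pipeline runs end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    mgcv,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
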