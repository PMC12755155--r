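Package: paygsim
Title: Pay-As-You-Go Pension Sustainability Under Pandemic Mortality Shocks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to assess the long-run financial sustainability of
    pay-as-you-go (PAYG) pension schemes under recurrent pandemic shocks.
    Age-specific mortality and fertility rates are modelled with a functional
    demographic model (a smoothed log-rate surface decomposed into a mean
    curve plus orthonormal principal-component basis functions whose scores
    are forecast by univariate time-series models). Pandemic mortality jumps,
    calibrated as per-age-group death-inflation ratios from a COVID-19-like
    reference event, are injected into the mortality forecasts on a fixed
    recurrence calendar. Populations are projected per gender in 5-year age
    groups through single-age cohort recursions equivalent to a Leslie matrix,
    yielding old-age dependency ratios and an annual contribution-versus-
    expenditure balance with scenario sensitivity (jump size, fertility level,
    unemployment level). A synthetic-data module generates realistic input
    bundles with known ground truth so the full pipeline is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
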