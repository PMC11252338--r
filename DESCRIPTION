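Package: qsarmlr
Title: Multiple Linear Regression QSAR Modelling with Full Internal and
    External Validation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits and validates multiple-linear-regression quantitative
    structure-activity relationship (QSAR) models of pIC50 from molecular
    descriptors. Provides backward descriptor elimination with variance
    inflation factor screening, leave-one-out cross-validation, the
    Golbraikh-Tropsha external-predictivity checklist, rm2 metrics,
    Y-randomization permutation testing with cRp2, and a leverage-based
    (Williams plot) applicability domain, together with screening of
    designed candidate compounds. Ships a worked dataset of
    1,2,4-triazin-3(2H)-one derivatives assayed against the MCF-7 breast
    cancer cell line, and a seedable synthetic-data generator for
    method-level testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
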