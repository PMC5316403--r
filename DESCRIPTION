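Package: cytotoxpanel
Title: Multicenter Concentration-Response Analysis for Acute Hepatotoxicity Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for multicenter in vitro cytotoxicity screens of
    drug-induced liver injury (DILI) compound panels. Fits the constrained
    two-parameter sigmoid (lower plateau 0, Hill coefficient -1) to
    vehicle-normalized viability data to estimate EC50s, compares dilution
    series with extra-sum-of-squares F-tests under a dual significance rule
    (p < 0.05 and EC50 ratio > 3-fold), computes inter-laboratory,
    intra-laboratory, inter-donor, clone and fresh-versus-cryopreserved
    variability coefficients, classifies compounds by the EC50/Cmax margin of
    safety, quantifies ATP-resorufin endpoint concordance, and clusters
    cell-model cytotoxicity profiles by complete-linkage hierarchical
    clustering. A seeded synthetic multicenter plate-data generator with known
    ground truth makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
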