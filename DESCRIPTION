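Package: edascreen
Title: Effect-Directed Analysis Screening of LC-HRMS Feature Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Data-processing workflow for high-throughput effect-directed
    analysis (EDA) of complex environmental and biological samples. Annotates
    aligned LC-HRMS feature tables against hierarchically applied suspect
    lists with a per-criterion total annotation quality (TAQ) code and
    Schymanski-style identification confidence levels; simulates isotope
    patterns and scores isotopic fit (mSigma-style); scores MS/MS library
    similarity and in-silico fragment matches; calls bioactive
    micro-fractions from 96-well plate bioassays; maps bioactive fractions
    to chromatographic retention-time windows; and prioritizes annotated
    features co-eluting with bioactivity, including retention-prediction
    box filtering of isomer candidates and confidence-level boosting. A
    synthetic-study generator produces complete input sets with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
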