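Package: flyfeedr
Title: Quantitative Analysis of Drosophila Feeding Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying short-term feeding behavior in Drosophila
    across four complementary assays: threshold-based detection of
    feeding-contact events in raw Fly Liquid-Food Interaction Counter (FLIC)
    traces with ground-truth validation, binned maximum delta-F/F analysis of
    ROI calcium-imaging time series with out-of-focus frame handling,
    dye-absorbance standard-curve calibration for converting optical density
    readings into ingested volumes, and bookkeeping for immobilized-fly
    pharyngeal pumping sessions (inclusion rules, feeding time, swallowing
    rate, pooled correlations). A synthetic-data module generates traces and
    cohorts with known ground truth so every analysis step can be exercised
    and benchmarked end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
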