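Package: fdgrepeat
Title: Quantification and Test-Retest Repeatability of Dynamic Brain FDG PET
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Quantifies dynamic [18F]FDG brain PET studies with arterial
    input: Patlak graphical analysis of the net influx rate and the cerebral
    metabolic rate of glucose, plateau standardized uptake values (SUV),
    glycemia-corrected SUV and reference-region SUV ratios. Implements the
    companion test-retest repeatability statistics (absolute variability,
    intra-/inter-subject variance decomposition, clipped 95% confidence
    intervals, precision-based sample sizes, exact small-sample Spearman and
    Wilcoxon tests, confidence-interval robustness checks) and a synthetic
    test-retest study generator with known ground-truth kinetics and
    variance components for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
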