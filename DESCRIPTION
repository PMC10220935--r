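Package: actipal
Title: Physical Activity Level from Triaxial Accelerometry with
    Sex-Specific Calibration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Processes raw waist-worn triaxial accelerometer signals into
    10-second epochs, classifies each epoch as sedentary, locomotive
    (ambulatory) or non-locomotive activity from the ratio of unfiltered to
    high-pass-filtered synthesized accelerations, assigns metabolic
    equivalents (METs) with published linear equations, detects non-wear
    time and valid days, and predicts basal metabolic rate, activity and
    total energy expenditure and the physical activity level (PAL) of
    community-dwelling older adults.  Includes the Nagayoshi MET
    adjustment, a sex-specific linear calibration of device-predicted PAL
    against reference (doubly-labeled-water style) PAL fitted by ordinary
    least squares, a synthetic signal and cohort generator with known
    ground truth, and validation statistics (prediction errors, Pearson
    correlations, paired comparisons).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
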