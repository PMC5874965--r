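Package: couchspc
Title: Statistical Process Control for Radiotherapy Couch-Positioning QA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for monitoring longitudinal couch-positioning quality
    assurance measurements on helical tomotherapy units with statistical
    process control. Fits individuals (X) control charts with moving-range
    control limits, tests windows for normality with the Anderson-Darling
    statistic, computes process capability (cp) and acceptability (cpk)
    indices against clinical action limits, partitions long QA logs into
    three-monthly windows for trend and pre/post-calibration phase
    comparison, and analyses applied-versus-detected couch offset
    experiments (linearity, cross-axis coupling, maximum deviation).
    Includes a seedable synthetic QA-log generator with injectable setup
    errors, encoder-fault shifts and drifts for validating every analysis
    stage against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    nortest,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
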