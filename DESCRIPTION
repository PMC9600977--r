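Package: counterpart3d
Title: Enlow Horizontal Counterpart Analysis on 2D and 3D Cephalometric
    Landmarks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements Enlow's horizontal counterpart analysis of craniofacial
    balance on named anatomical landmark coordinates, in its classical
    two-dimensional form on lateral-cephalogram landmarks and in a
    three-dimensional form on CBCT-derived landmarks, where every length is a
    point-to-plane distance against planes built from three geometric
    construction rules. Provides part-minus-counterpart discrepancy scoring
    with the 2.5 mm harmony classification, cohort statistics (Kolmogorov-
    Smirnov normality and paired Student's t) comparing 2D against 3D
    discrepancies, a seeded synthetic skull-landmark generator with planted
    part lengths and a lateral-projection model for validation, and readers
    and writers for CSV, JSON and 3D Slicer FCSV landmark files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    nortest,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
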