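Package: mmpipe
Title: Automated Analysis of Mother Machine Time-Lapse Image Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Automated processing of mother machine (MM) microfluidic
    time-lapse image stacks: frame registration by 1D profile
    cross-correlation, orientation correction, frequency-domain growth
    channel detection, 1D intensity-profile cell detection with
    length/blackness/prominence filtering, lineage tracking as a
    constrained assignment problem solved greedily, and single-cell
    quantification (division times, growth rates, fluorescence).
    Includes a synthetic scene simulator that renders MM stacks with
    full ground truth so every pipeline stage can be validated without
    external data, plus kymograph visualisation and tabular export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    tiff,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
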