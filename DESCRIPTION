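Package: avcscore
Title: Aortic Valve Calcium Scoring on Native and Contrast-Enhanced CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies aortic valve calcification (AVC) on cardiac CT.
    Implements the classic Agatston score on native (non-contrast) scans,
    a patient-specific dynamic Hounsfield-unit threshold (aortic luminal
    attenuation plus four standard deviations) for segmenting valve calcium
    on contrast-enhanced scans, and a linear conversion from contrast-enhanced
    calcium volume to calculated Agatston units. Ships method-agreement
    statistics (two-way intraclass correlation with confidence intervals,
    Bland-Altman analysis with a proportional-bias test) for validating
    conversions against native scoring, plus a synthetic CT phantom generator
    with exact calcium ground truth for end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    tibble,
    dplyr,
    purrr,
    ggplot2,
    generics,
    igraph,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    withr
Config/testthat/edition: 3
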