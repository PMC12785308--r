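Package: trichobench
Title: Anti-Leakage Image Transformation and Reader-Study Statistics for
    Trichoscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for head-to-head diagnostic reader studies on
    trichoscopic (scalp dermoscopy) images. Provides a reproducible
    ten-stage image transformation pipeline that renders images
    unrecognizable to pretrained vision models while preserving
    diagnostic morphology, quantitative integrity verification of the
    transformed images (structural similarity and perceptual hashes),
    scoring of suspected/differential diagnosis responses against ground
    truth, diagnostic-accuracy estimation with Wilson score confidence
    intervals, group comparisons via Pearson chi-square or Fisher's exact
    test with Holm-Bonferroni post hoc adjustment, and Gwet's AC1
    chance-corrected inter-rater agreement for binary ratings. Includes
    generators for synthetic scalp-like images with known ground truth
    and for simulated rater-response data, so the full analysis can be
    exercised end to end without access to clinical images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
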