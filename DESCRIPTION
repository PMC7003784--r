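Package: facemap
Title: Pixelwise Relevance and Significance Mapping of Facial Skin Colour Change
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Quantifies facial skin colour change between two time points of
    a controlled study from cross-polarized photographs. Images are
    colour-corrected against an in-frame 48-patch reference chart, brought
    into a common anatomical reference space by landmark-based thin-plate
    spline registration (right facial sides mirrored onto the left), and
    averaged per group and time point. For every pixel the package computes
    the CIELAB change, the CIE76 colour difference (Delta E) relevance map
    with its visibility threshold, and paired t-test significance maps
    hue-coded by direction of change. A classical four-region comparator
    (paired t and Wilcoxon signed-rank tests on region means) and a
    deterministic synthetic-study generator are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    tiff,
    yaml,
    stats,
    tools,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
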