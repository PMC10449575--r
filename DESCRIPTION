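Package: apoiabs
Title: Multi-Attribute Utility Scoring of Biostimulant Field Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A scoring engine for multi-attribute agro-environmental
    assessment of crop biostimulants in paired control-versus-treatment
    field trials.  Converts per-indicator measurements into impact
    (percent-change) and technical-performance (treatment-level) utility
    indices on a 0-1 scale anchored at a 0.7 baseline, aggregates them
    over five analytical themes (crop production, soil chemistry, soil
    physics, soil biology, plant health), and provides cross-case
    analytics: a Pearson correlation significance matrix and principal
    component analysis with Kaiser-criterion component retention.
    Includes a synthetic paired-trial generator with known planted
    effect sizes for validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
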