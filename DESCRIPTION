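Package: vasodyn
Title: Quantification of Vascular Dynamics from Intravital Fluorescence
    Angiography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify electroporation-induced vascular effects in
    time-lapse fluorescence angiography of the mouse dorsal window chamber:
    vessel-network segmentation into vascular and tissue compartments,
    tracer filling-up kinetics (percent of maximal vascular intensity,
    completion time, maximal intensity variation per second), tissue
    extravasation kinetics (relative intensity variation, per-minute leakage
    rates, linear-plateau segmented regression), full-width-at-half-maximum
    vessel diameter morphometry with baseline normalization, and the group
    statistics used in this field (per-timepoint t tests with a sustained
    recovery-time rule, one-way ANOVA followed by the Holm-Sidak step-down
    procedure).  A synthetic angiography generator with complete ground
    truth emulates the acquisition protocol (pre-injection frames every 20 s
    for 2 min; post-pulse frames every 20 s for 8 min then every 2 min for
    22 min) and the vascular lock, vasoconstriction and leakage phenomena,
    so every estimator can be validated by parameter recovery at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
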