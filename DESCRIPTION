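Package: vasotherm
Title: Linking Body-Surface Temperature to Sympathetic Activation from
    Thermal Imaging and Heart-Rate Variability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing stress-induced peripheral vasoconstriction
    from synchronized infrared thermography and ECG telemetry. Converts beat
    detections into cleaned R-R intervals, heart rate and rolling
    coefficient-of-variation heart-rate variability on a millisecond grid;
    extracts, reference-calibrates and quality-filters regional maximum
    surface temperatures (eye ring, bill) from 16-bit radiometric frames;
    aligns the two streams into analysis periods under explicit inclusion
    rules; and fits linear mixed-effects models of temperature on
    heart-rate variability with residual temporal correlation, all-subsets
    selection and AIC model averaging. A synthetic-data generator with known
    ground-truth coupling makes every stage verifiable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    nlme,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    patchwork,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
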