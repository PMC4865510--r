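Package: dcltools
Title: Multimodal Driving-Fatigue Analysis with the Driving Condition Level
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify driver mental fatigue from simultaneous
    EEG/ECG/EOG and prefrontal fNIRS recordings. Implements relative
    band-power extraction from EEG, R-peak based heart-rate and RR-interval
    features from ECG, blink-rate features from EOG, conversion of
    two-wavelength near-infrared light intensities to oxy-/deoxy-hemoglobin
    concentration changes via the modified Beer-Lambert law, the Driving
    Condition Level (DCL) fatigue index with min-max normalization and
    outlier shrinkage, and Fisher linear discriminant classification of
    well-rested versus sleep-deprived sessions with time-ordered sliding
    splits and stacked multimodal fusion. A seeded synthetic multimodal
    signal generator with ground-truth event lists makes the whole pipeline
    testable end to end, and EDF/delimited-text readers and writers cover
    the on-disk formats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
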