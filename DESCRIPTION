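Package: perclosr
Title: EEG-Based Eyelid Closure Estimation and PERCLOS Drowsiness Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the eyelid closure degree (ECD) of a driver from
    occipital EEG instead of video. Implements spectral (band power
    percentage) and time-domain (RMS, Shannon entropy) feature extraction,
    blink-spike removal from ECD traces, ECD group labelling and segment
    selection, simple linear and epsilon-insensitive support vector
    regression of ECD on alpha-band power, leave-one-subject-out
    evaluation with Bland-Altman agreement and subgroup comparisons, and
    the derived real-time EEG-based PERCLOS drowsiness alarm. A seeded
    synthetic-data generator emulates 7 Hz eyelid traces and 128 Hz
    multichannel EEG whose band composition tracks eyelid closure, so the
    whole pipeline is testable without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
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
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
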