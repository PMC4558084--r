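Package: phonoseg
Title: Heart Sound Segmentation and Timing Diagnostics for Phonocardiograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segments the first (S1) and second (S2) heart sounds from
    single-channel phonocardiogram (PCG) audio using a spectral-flux onset
    strength envelope and two-pass dynamic-programming beat tracking with a
    global tempo, then derives the diagnostic timing parameters: heartbeat
    interval (T11), systolic interval (T12), diastolic interval (T21 = T11 -
    T12), heart sound widths (T1, T2) from the Shannon energy envelope, and
    the systole/diastole ratio r = T12 / (T11 - T12).  Includes WAV input and
    band-limiting preprocessing, S1 identification by timing rules and
    infrasonic-band variance, report building with configurable nominal
    regions, a seeded synthetic-PCG generator with ground truth for
    end-to-end evaluation, and detection scoring (recall, precision, timing
    RMSE).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
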