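Package: cisim
Title: Acoustic Simulation of Cochlear-Implant Sound
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Signal-processing toolbox that transforms speech recordings into
    acoustic approximations of cochlear-implant (CI) hearing. Provides causal
    Butterworth pass filters and feedback comb filters on clinical parameter
    grids, duration-preserving pitch shifting, single-sideband frequency
    shifting, overmodulation/clipping, and two 22-channel vocoders (an
    ACE-style FFT filter-bank vocoder with n-of-m maxima selection and a
    band-pass filter-bank vocoder), each with sine or seeded-noise carriers
    and spread-of-excitation control. Ships reconstructed screening and
    participant-optimized parameter-set catalogs, a generator for the
    100-stimulus screening battery with seeded randomization, and a
    license-free synthetic speech-like sentence generator for testing.
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
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
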