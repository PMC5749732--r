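Package: circatrack
Title: Single-Cell Circadian Bioluminescence Analysis Under Temperature Cycles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for quantitative single-cell circadian analysis of
    bioluminescence recordings under temperature-cycle (T-cycle) entrainment
    protocols. Turns time-lapse image stacks or per-cell intensity tables into
    periods, phases, phase shifts, phase-response and amplitude-response
    curves, and circular statistics. Includes temporal (Kalman-type) stack
    denoising, median outlier removal, dynamic-programming spot tracking,
    running-average detrending, FFT-seeded nonlinear least-squares cosine
    fitting, parabolic peak picking, circadian-time conversions, Rayleigh and
    Watson-Williams tests, and a ground-truthed synthetic-data generator
    (coupled stochastic Poincare oscillators plus a bioluminescence movie
    renderer) for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    minpack.lm,
    jsonlite,
    yaml,
    readr,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
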