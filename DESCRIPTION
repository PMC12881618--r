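Package: spiralpam
Title: Desk-Scale Simulator and Analysis Toolkit for Spiral-Scanning
    Photoacoustic Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the computational core of a handheld fiber-scanning
    photoacoustic microscope: resonant-cantilever spiral trajectories with
    imaging, active-braking and free-decay phases; stepped pulse-repetition-
    frequency laser triggering with per-pixel illumination-density and
    fill-factor analysis; KLM transmission-line modelling of a layered
    transparent ultrasound transducer with -6 dB band metrics; procedural
    phantoms (vessel trees, edge, grid and point targets); synthetic A-scan
    acquisition; position-based three-case volume reconstruction with
    maximum-amplitude and depth-encoded projections; and image-quality and
    vessel-morphometry quantification (resolution from edge/line spread
    functions, SNR, area/skeleton/diameter/complexity indices, macro/micro
    vessel splits and frame-series analysis).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
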