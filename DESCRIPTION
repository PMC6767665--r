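Package: dcoct
Title: Dual-Channel Spectral-Domain OCT Simulation and Compressive
    Dispersion-Encoded Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates spectral-domain optical coherence tomography (SD-OCT)
    interferograms in which two depth channels are encoded into a single
    spectrometer spectrum via a pre-introduced reference path offset and a
    deliberate cubic dispersion phase, and reconstructs full-range,
    conjugate-artifact-free depth profiles from randomly undersampled spectra
    using a two-step compressive dispersion-encoding (TCDE) algorithm.
    Includes sparse and layered phantom generators, spectral grid utilities
    with wavelength-to-wavenumber resampling, random spectral sampling masks,
    dual-channel demultiplexing and B-scan stitching for the speed and depth
    imaging modes, an A-scan SNR metric, and an analytic design calculator
    for the system's resolution and depth figures.
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
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    png,
    testthat (>= 3.0.0),
    tiff,
    withr,
    yaml
Config/testthat/edition: 3
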